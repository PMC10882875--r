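# Directed disease trajectory network: assembly from selected pairs,
# cycle-safe path chaining, linear three-disease trajectories with patient
# counts and median inter-onset gaps, and plain-text / GraphML exports.

#' Build the disease trajectory network
#'
#' Assembles selected directed pairs into a graph whose nodes carry patient
#' counts (persons ever diagnosed with the disease in the cohort) and whose
#' edges carry the matched odds ratio and its confidence interval.  Nodes
#' are classified by role: `start` (out-edges only), `end` (in-edges only),
#' `middle` otherwise; total degree gives the hub ranking (`degree_rank`),
#' whose top entries are the network's "center".
#'
#' @param selected Data frame with columns `source`, `target` and
#'   (optionally) `or`, `ci_low`, `ci_high` — e.g. the selected rows of
#'   [estimate_all_pairs()].
#' @param cohort A `traj_cohort` supplying the node patient counts.
#' @return An object of class `trajectory_network`: a list with data frames
#'   `nodes` (`disease`, `n_patients`, `in_degree`, `out_degree`, `role`,
#'   `degree_rank`) and `edges` (`source`, `target`, `or`, `ci_low`,
#'   `ci_high`).
#' @export
build_network <- function(selected, cohort = NULL) {
  edges <- data.frame(
    source = as.character(selected$source),
    target = as.character(selected$target),
    or = if ("or" %in% names(selected)) selected$or else NA_real_,
    ci_low = if ("ci_low" %in% names(selected)) selected$ci_low
             else NA_real_,
    ci_high = if ("ci_high" %in% names(selected)) selected$ci_high
              else NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) traj_warning("building an empty network")
  if (any(edges$source == edges$target))
    traj_error("trajnet_validation_error", "self-loop edges are not allowed")
  if (any(!is.na(edges$or) & edges$or <= 1))
    traj_error("trajnet_validation_error",
               "network edges must have OR > 1 (selection rule)")
  nodes <- sort(unique(c(edges$source, edges$target)))
  n_pat <- if (!is.null(cohort)) {
    vapply(nodes, function(d)
      length(unique(cohort$events$person_id[cohort$events$disease == d])),
      integer(1))
  } else rep(NA_integer_, length(nodes))
  indeg <- as.vector(table(factor(edges$target, levels = nodes)))
  outdeg <- as.vector(table(factor(edges$source, levels = nodes)))
  role <- ifelse(indeg == 0L & outdeg > 0L, "start",
                 ifelse(outdeg == 0L & indeg > 0L, "end", "middle"))
  deg <- indeg + outdeg
  nodes_df <- data.frame(disease = nodes, n_patients = n_pat,
                         in_degree = indeg, out_degree = outdeg,
                         role = role,
                         degree_rank = rank(-deg, ties.method = "min"),
                         stringsAsFactors = FALSE)
  rownames(nodes_df) <- NULL
  structure(list(nodes = nodes_df, edges = edges),
            class = "trajectory_network")
}

#' @export
print.trajectory_network <- function(x, ...) {
  cat(sprintf("<trajectory_network> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  starts <- x$nodes$disease[x$nodes$role == "start"]
  ends <- x$nodes$disease[x$nodes$role == "end"]
  if (length(starts)) cat("start nodes:", paste(starts, collapse = ", "), "\n")
  if (length(ends)) cat("end nodes:  ", paste(ends, collapse = ", "), "\n")
  invisible(x)
}

#' Chain directed trajectories through shared nodes
#'
#' Enumerates every simple directed path of 2 up to `max_length` nodes: if
#' d1 -> d2 and d2 -> d3 are edges, the chained trajectory d1 -> d2 -> d3
#' is produced, and so on.  Enumeration is cycle-safe: a path never
#' revisits a node; when an edge closing a cycle is encountered the path is
#' truncated there and the result carries `has_cycles = TRUE`.
#'
#' @param network A `trajectory_network`.
#' @param max_length Maximum number of nodes per path (default 4).
#' @return A list of character vectors (each a node sequence), sorted
#'   deterministically, with attribute `has_cycles`.
#' @export
chain_trajectories <- function(network, max_length = 4L) {
  stopifnot(inherits(network, "trajectory_network"), max_length >= 2L)
  edges <- network$edges
  adj <- split(edges$target, edges$source)
  adj <- lapply(adj, sort)
  paths <- list()
  has_cycle <- FALSE
  dfs <- function(path) {
    nxts <- adj[[path[length(path)]]]
    for (nxt in nxts) {
      if (nxt %in% path) { has_cycle <<- TRUE; next }
      p2 <- c(path, nxt)
      paths[[length(paths) + 1L]] <<- p2
      if (length(p2) < max_length) dfs(p2)
    }
  }
  for (v in network$nodes$disease) dfs(v)
  keys <- vapply(paths, paste, character(1), collapse = " -> ")
  paths <- paths[order(lengths(paths), keys)]
  attr(paths, "has_cycles") <- has_cycle
  paths
}

#' Linear three-disease trajectories with counts and median gaps
#'
#' For every 3-node path d1 -> d2 -> d3 of the network, counts the cohort
#' members following the stem and the full chain in strict onset order and
#' summarizes the inter-onset gaps:
#'
#' * `n_12`: persons with d1 strictly before d2 (anywhere in the cohort);
#' * `median_t12`: median of (d2 onset age - d1 onset age) among them;
#' * `median_onset_age_d1`: median d1 onset age among those `n_12` persons
#'   (set `age_basis = "full"` to compute it among the `n_123` persons
#'   instead);
#' * `n_123`: persons with d1 < d2 < d3 strictly;
#' * `median_t23`: median of (d3 - d2) among them (`NA` when `n_123` is 0).
#'
#' @param cohort A `traj_cohort`.
#' @param network A `trajectory_network`.
#' @param age_basis `"stem"` (default) or `"full"` — the sub-cohort over
#'   which the median d1 onset age is taken.
#' @return Data frame with one row per 3-node path.
#' @export
linear_trajectories <- function(cohort, network,
                                age_basis = c("stem", "full")) {
  stopifnot(inherits(cohort, "traj_cohort"))
  age_basis <- match.arg(age_basis)
  triples <- Filter(function(p) length(p) == 3L,
                    chain_trajectories(network, max_length = 3L))
  om <- onset_matrix(cohort, network$nodes$disease)
  rows <- lapply(triples, function(tr) {
    o1 <- om[, tr[1]]; o2 <- om[, tr[2]]; o3 <- om[, tr[3]]
    s12 <- !is.na(o1) & !is.na(o2) & o1 < o2
    s123 <- s12 & !is.na(o3) & o2 < o3
    n12 <- sum(s12); n123 <- sum(s123)
    data.frame(
      d1 = tr[1], d2 = tr[2], d3 = tr[3],
      median_onset_age_d1 = if (age_basis == "stem") {
        if (n12) stats::median(o1[s12]) else NA_real_
      } else {
        if (n123) stats::median(o1[s123]) else NA_real_
      },
      n_12 = n12,
      median_t12 = if (n12) stats::median(o2[s12] - o1[s12]) else NA_real_,
      n_123 = n123,
      median_t23 = if (n123) stats::median(o3[s123] - o2[s123])
                   else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(d1 = character(), d2 = character(), d3 = character(),
               median_onset_age_d1 = numeric(), n_12 = integer(),
               median_t12 = numeric(), n_123 = integer(),
               median_t23 = numeric())
  rownames(out) <- NULL
  out
}

#' Rank linear trajectories
#'
#' Sorts by the number of patients completing the full three-disease chain
#' (descending), breaking ties by the stem count (descending) and then the
#' lexicographic path, and returns the top `k` with a `rank` column.
#'
#' @param rows Data frame from [linear_trajectories()].
#' @param k Number of rows to return (default 10).
#' @return The top-`k` rows with a leading `rank` column.
#' @export
rank_trajectories <- function(rows, k = 10L) {
  ord <- order(-rows$n_123, -rows$n_12, rows$d1, rows$d2, rows$d3)
  out <- rows[ord, , drop = FALSE]
  out <- utils::head(out, k)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Export a trajectory network
#'
#' `"edgelist"` writes a tagged tab-separated file (node and edge records
#' with their attributes) that [import_network()] reads back losslessly;
#' `"graphml"` writes GraphML (via igraph) with `n_patients` on nodes and
#' `or`, `ci_low`, `ci_high` on edges, for generic graph viewers.
#'
#' @param network A `trajectory_network`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("edgelist",
                                                     "graphml")) {
  stopifnot(inherits(network, "trajectory_network"))
  if (length(format) == 1L && !format %in% c("edgelist", "graphml"))
    traj_error("trajnet_validation_error",
               sprintf("unknown export format '%s'", format))
  format <- match.arg(format)
  if (format == "edgelist") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# trajnet network export v1", con)
    nd <- network$nodes
    for (i in seq_len(nrow(nd)))
      writeLines(paste("node", nd$disease[i], nd$n_patients[i],
                       sep = "\t"), con)
    eg <- network$edges
    for (i in seq_len(nrow(eg)))
      writeLines(paste("edge", eg$source[i], eg$target[i], eg$or[i],
                       eg$ci_low[i], eg$ci_high[i], sep = "\t"), con)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a trajectory network to an igraph object
#'
#' @param network A `trajectory_network`.
#' @return A directed `igraph` graph with the node and edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "trajectory_network"))
  igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = network$nodes[, c("disease", "n_patients")])
}

#' Import a trajectory network exported as an edge list
#'
#' @param path File written by [export_network()] with
#'   `format = "edgelist"`.
#' @return A `trajectory_network` (roles and degree ranks recomputed).
#' @export
import_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, character(1), 1L)
  nodes <- do.call(rbind, lapply(parts[tag == "node"], function(x)
    data.frame(disease = x[2],
               n_patients = suppressWarnings(as.integer(x[3])),
               stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(parts[tag == "edge"], function(x)
    data.frame(source = x[2], target = x[3],
               or = suppressWarnings(as.numeric(x[4])),
               ci_low = suppressWarnings(as.numeric(x[5])),
               ci_high = suppressWarnings(as.numeric(x[6])),
               stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        or = numeric(), ci_low = numeric(),
                        ci_high = numeric())
  net <- suppressWarnings(build_network(edges))
  if (!is.null(nodes)) {
    idx <- match(net$nodes$disease, nodes$disease)
    net$nodes$n_patients <- nodes$n_patients[idx]
  }
  net
}
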