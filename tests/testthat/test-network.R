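edges_df <- function(src, tgt, or = 2) {
  or <- rep_len(or, length(src))
  data.frame(source = src, target = tgt, or = or, ci_low = or * 0.8,
              ci_high = or * 1.3, stringsAsFactors = FALSE)
}

test_that("build_network classifies roles and counts patients", {
  parts <- mk_participants(c("x", "y"), entry_age = 45, exit_age = 70)
  ev <- rbind(mk_events("x", c("arthritis", "hypertension"), c(50, 55)),
              mk_events("y", "arthritis", 52))
  co <- mk_cohort(parts, ev)
  net <- build_network(edges_df(c("arthritis", "hypertension"),
                                c("hypertension", "stroke")), co)
  roles <- setNames(net$nodes$role, net$nodes$disease)
  expect_equal(roles[["arthritis"]], "start")
  expect_equal(roles[["stroke"]], "end")
  expect_equal(roles[["hypertension"]], "middle")
  counts <- setNames(net$nodes$n_patients, net$nodes$disease)
  expect_equal(counts[["arthritis"]], 2L)
  expect_equal(counts[["stroke"]], 0L)
  # the highest-degree node ranks first (the network's "center")
  expect_equal(net$nodes$disease[net$nodes$degree_rank == 1],
               "hypertension")

  expect_error(build_network(edges_df("a", "a")),
               class = "trajnet_validation_error")
  expect_error(build_network(edges_df("a", "b", or = 0.9)),
               class = "trajnet_validation_error")
  expect_warning(build_network(edges_df(character(), character())),
                 "empty")
})

test_that("chain_trajectories chains shared nodes and is cycle-safe", {
  net <- build_network(edges_df(c("a", "b", "c"), c("b", "c", "d")))
  paths <- chain_trajectories(net, max_length = 4)
  keys <- vapply(paths, paste, character(1), collapse = ">")
  expect_true("a>b>c>d" %in% keys)
  expect_false(attr(paths, "has_cycles"))

  single <- chain_trajectories(build_network(edges_df("a", "b")), 4)
  expect_equal(length(single), 1L)
  expect_equal(single[[1]], c("a", "b"))

  # 2-cycle: both 2-node paths, cycle flagged, no infinite loop
  cyc <- chain_trajectories(build_network(edges_df(c("a", "b"),
                                                   c("b", "a"))), 5)
  expect_setequal(vapply(cyc, paste, character(1), collapse = ">"),
                  c("a>b", "b>a"))
  expect_true(attr(cyc, "has_cycles"))
})

test_that("chain_trajectories equals brute-force DFS on random graphs", {
  set.seed(77)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    nodes <- letters[1:k]
    adj <- matrix(rbinom(k * k, 1, 0.4), k, k,
                  dimnames = list(nodes, nodes))
    diag(adj) <- 0
    idx <- which(adj == 1, arr.ind = TRUE)
    if (!nrow(idx)) next
    net <- build_network(edges_df(nodes[idx[, 1]], nodes[idx[, 2]]))
    got <- chain_trajectories(net, max_length = k)
    want <- brute_paths(adj, k)
    expect_equal(lapply(got, unname), want)
  }
})

test_that("linear trajectories match per-person ordering enumeration", {
  parts <- mk_participants(sprintf("p%d", 1:5), entry_age = 45,
                           exit_age = 75)
  ev <- rbind(
    mk_events("p1", c("arthritis", "hypertension", "stroke"),
              c(50, 58, 64)),
    mk_events("p2", c("arthritis", "hypertension", "stroke"),
              c(52, 60, 60)),                      # d2/d3 tie: stem only
    mk_events("p3", c("arthritis", "hypertension"), c(47, 57)),
    mk_events("p4", c("hypertension", "arthritis"), c(50, 55)),  # reversed
    mk_events("p5", c("arthritis", "stroke"), c(49, 51)))
  co <- mk_cohort(parts, ev)
  net <- build_network(edges_df(c("arthritis", "hypertension"),
                                c("hypertension", "stroke")), co)
  lt <- linear_trajectories(co, net)
  expect_equal(nrow(lt), 1L)
  # hand enumeration: p1, p2, p3 follow arthritis<hypertension strictly
  expect_equal(lt$n_12, 3L)
  expect_equal(lt$median_t12, 8)           # gaps 8, 8, 10
  expect_equal(lt$median_onset_age_d1, 50) # ages 50, 52, 47
  # only p1 completes the chain strictly
  expect_equal(lt$n_123, 1L)
  expect_equal(lt$median_t23, 6)
  # alternative basis: age among completers
  lt2 <- linear_trajectories(co, net, age_basis = "full")
  expect_equal(lt2$median_onset_age_d1, 50)

  # nobody follows the chain: absent medians, zero count
  net2 <- build_network(edges_df(c("stroke", "hypertension"),
                                 c("hypertension", "arthritis")), co)
  lt3 <- linear_trajectories(co, net2)
  expect_equal(lt3$n_123, 0L)
  expect_true(is.na(lt3$median_t23))
})

test_that("rank_trajectories sorts, breaks ties and truncates", {
  rows <- data.frame(
    d1 = c("a", "b", "c", "d"), d2 = "x", d3 = c("z", "z", "y", "w"),
    median_onset_age_d1 = 50, n_12 = c(100, 90, 90, 100),
    median_t12 = 5, n_123 = c(446, 389, 328, 389), median_t23 = 4,
    stringsAsFactors = FALSE)
  top <- rank_trajectories(rows, k = 10)
  expect_equal(top$n_123, c(446, 389, 389, 328))
  expect_equal(top$d1, c("a", "d", "b", "c"))  # tie: larger n_12 first
  expect_equal(top$rank, 1:4)
  expect_equal(nrow(rank_trajectories(rows, k = 2)), 2L)
})

test_that("network exports round-trip and produce valid GraphML", {
  parts <- mk_participants(c("x", "y"), entry_age = 45, exit_age = 70)
  ev <- rbind(mk_events("x", c("arthritis", "hypertension"), c(50, 55)),
              mk_events("y", "arthritis", 52))
  net <- build_network(edges_df(c("arthritis", "hypertension"),
                                c("hypertension", "stroke")),
                       mk_cohort(parts, ev))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "edgelist")
  back <- import_network(f)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)

  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, g, "graphml")
  doc <- xml2::read_xml(g)                 # well-formed XML
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_match(paste(unlist(xml2::xml_ns(doc)), collapse = " "),
               "graphml", ignore.case = TRUE)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(gg), 2)
  expect_setequal(igraph::vertex_attr(gg, "name"), net$nodes$disease)

  expect_error(export_network(net, f, "dot"),
               class = "trajnet_validation_error")

  # empty network still exports a valid file
  e <- withr::local_tempfile(fileext = ".tsv")
  empty <- suppressWarnings(build_network(edges_df(character(),
                                                   character())))
  export_network(empty, e, "edgelist")
  expect_equal(nrow(import_network(e)$edges), 0L)
})
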