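# End-to-end orchestration: clean -> describe -> direction -> match/OR ->
# network -> linear trajectories, with every intermediate table written to
# disk under a deterministic header (package version, seed, config hash),
# plus a small subcommand-style CLI front end.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to cohort files) or `simulation` (a
#' [sim_config()]) must be supplied.
#'
#' @param input `NULL`, or `list(events = path, participants = path,
#'   sep = ",")`.
#' @param simulation `NULL`, or a [sim_config()].
#' @param exclusions Exclusion-rule flags passed to [apply_exclusions()].
#' @param direction_policy Threshold policy for [direction_test_all()].
#' @param alpha Base significance level for the direction test.
#' @param match A [match_config()]; its seed is re-derived from `seed`.
#' @param max_path_length Maximum nodes per chained trajectory.
#' @param top_k Rows kept by [rank_trajectories()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            exclusions = list(no_followup = TRUE,
                                              missing_demog = TRUE),
                            direction_policy = "bonferroni", alpha = 0.05,
                            match = match_config(),
                            max_path_length = 4L, top_k = 10L,
                            out_dir = tempfile("trajnet_run_"),
                            seed = 1L, verbose = FALSE) {
  structure(list(input = input, simulation = simulation,
                 exclusions = exclusions,
                 direction_policy = direction_policy, alpha = alpha,
                 match = match, max_path_length = max_path_length,
                 top_k = top_k, out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Cross-field checks with human-readable findings; an empty character
#' vector means the configuration is valid.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems (possibly empty).
#' @export
validate_config <- function(config) {
  problems <- character()
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim)
    problems <- c(problems,
                  "exactly one of input paths or a simulation config is required")
  if (has_input &&
      !all(c("events", "participants") %in% names(config$input)))
    problems <- c(problems, "input needs elements 'events' and 'participants'")
  if (has_sim && !inherits(config$simulation, "sim_config"))
    problems <- c(problems, "simulation must be a sim_config object")
  if (!inherits(config$match, "match_config"))
    problems <- c(problems, "match must be a match_config object")
  else if (config$match$ratio < 1)
    problems <- c(problems, "ratio >= 1 required")
  if (!config$direction_policy %in% c("bonferroni", "per_pair_n", "fixed"))
    problems <- c(problems, "unknown direction threshold policy")
  if (!(config$alpha > 0 && config$alpha < 1))
    problems <- c(problems, "alpha must lie in (0,1)")
  if (config$max_path_length < 2)
    problems <- c(problems, "max_path_length must be at least 2")
  if (config$top_k < 1)
    problems <- c(problems, "top_k must be at least 1")
  problems
}

config_hash <- function(config) {
  x <- unclass(config)
  # fingerprint the scientific configuration only: where the outputs land
  # and how chatty the run is must not change the recorded identity
  x$out_dir <- NULL
  x$verbose <- NULL
  sort_fn <- function(v) {
    if (is.list(v)) lapply(v[order(names(v))], sort_fn) else v
  }
  str_hash32(jsonlite::toJSON(sort_fn(x), auto_unbox = TRUE, force = TRUE,
                              digits = NA))
}

write_stage_table <- function(df, path, seed, hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# trajnet %s seed=%d config=%s",
                     as.character(utils::packageVersion("trajnet")),
                     seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full trajectory-network pipeline
#'
#' Executes, in order: cohort acquisition (read or simulate), exclusions,
#' descriptives, pairwise direction testing, matched conditional-logistic
#' OR estimation with bootstrap intervals, network assembly, and linear
#' trajectory ranking.  Every stage's table is written under
#' `config$out_dir` with a header carrying the package version, master seed
#' and a hash of the configuration, so two runs with the same config are
#' byte-identical.  A stage failure preserves the outputs written so far
#' and is recorded in the returned report.
#'
#' @param config A [pipeline_config()].
#' @return A run report (list): stage counts, thresholds, seeds, selected
#'   edges, the ranked trajectory table, output paths, and `failed_stage`
#'   (`NA` on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems))
    traj_error("trajnet_config_error", paste(problems, collapse = "; "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (config$verbose) message(sprintf(...))
  report <- list(seed = config$seed, config_hash = hash,
                 out_dir = config$out_dir, failed_stage = NA_character_,
                 counts = list(), thresholds = list(
                   direction_policy = config$direction_policy,
                   alpha = config$alpha))
  emit <- function(df, name)
    write_stage_table(df, file.path(config$out_dir, name), config$seed,
                      hash)
  stage <- function(name, fun) {
    say("stage: %s", name)
    tryCatch(fun(), error = function(e) {
      report$failed_stage <<- name
      traj_warning(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
      NULL
    })
  }

  # --- acquire ---------------------------------------------------------
  cohort <- stage("acquire", function() {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, 1L)
      res <- simulate_cohort(sim)
      report$ground_truth <<- res$ground_truth
      res$cohort
    } else {
      read_cohort(config$input$events, config$input$participants,
                  sep = config$input$sep %||% ",")
    }
  })
  if (is.null(cohort)) return(report)
  write_cohort(cohort, file.path(config$out_dir, "events_raw.csv"),
               file.path(config$out_dir, "participants_raw.csv"))

  # --- clean -----------------------------------------------------------
  cleaned <- stage("clean", function() {
    res <- suppressWarnings(apply_exclusions(cohort, config$exclusions))
    report$counts$exclusions <<- res$log
    emit(as.data.frame(res$log), "exclusion_log.csv")
    res$cohort
  })
  if (is.null(cleaned)) return(report)
  write_cohort(cleaned, file.path(config$out_dir, "events.csv"),
               file.path(config$out_dir, "participants.csv"))
  report$counts$participants <- nrow(cleaned$participants)
  report$counts$events <- nrow(cleaned$events)
  empty_cohort <- nrow(cleaned$participants) == 0L ||
    nrow(cleaned$events) == 0L
  if (empty_cohort)
    traj_warning("cohort has no participants or no events; downstream stages will be empty")

  # --- describe --------------------------------------------------------
  stage("describe", function() {
    if (empty_cohort) return(NULL)
    fo <- first_onsets(cleaned)
    emit(fo, "first_onsets.csv")
    emit(onset_age_summary(fo), "onset_age_summary.csv")
    emit(onset_age_histogram(cleaned), "onset_age_histogram.csv")
    mm <- multimorbidity_distribution(cleaned)
    emit(data.frame(category = names(mm), percent = as.numeric(mm)),
         "multimorbidity.csv")
    NULL
  })

  # --- direction -------------------------------------------------------
  directions <- stage("direction", function() {
    if (empty_cohort)
      return(data.frame(source = character(), target = character(),
                        significant = logical()))
    res <- direction_test_all(cleaned, policy = config$direction_policy,
                              alpha = config$alpha)
    emit(res, "direction_tests.csv")
    res
  })
  if (is.null(directions)) return(report)
  directed <- select_directed_pairs(directions)
  report$counts$pairs_tested <- nrow(directions)
  report$counts$pairs_directed <- nrow(directed)

  # --- pairs (matched ORs) --------------------------------------------
  estimates <- stage("pairs", function() {
    cfg <- config$match
    cfg$seed <- derive_seed(config$seed, 2L)
    res <- estimate_all_pairs(cleaned, directed, cfg)
    emit(res, "pair_estimates.csv")
    res
  })
  if (is.null(estimates)) return(report)
  selected <- estimates[estimates$selected %in% TRUE, , drop = FALSE]
  report$counts$edges_selected <- nrow(selected)
  report$selected_edges <- selected

  # --- network + trajectories -----------------------------------------
  stage("network", function() {
    net <- suppressWarnings(build_network(selected, cleaned))
    export_network(net, file.path(config$out_dir, "network_edgelist.tsv"),
                   "edgelist")
    if (nrow(net$edges))
      export_network(net, file.path(config$out_dir, "network.graphml"),
                     "graphml")
    report$network <<- net
    lt <- linear_trajectories(cleaned, net)
    ranked <- rank_trajectories(lt, config$top_k)
    emit(lt, "linear_trajectories.csv")
    emit(ranked, "trajectories_top.csv")
    report$trajectories <<- ranked
    report$counts$trajectories_ranked <<- nrow(ranked)
    NULL
  })

  report
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `trajnet` script shipped under
#' `inst/cli/`: `trajnet <subcommand> --config FILE [--seed S] [--out DIR]`.
#' `run-all` executes the whole pipeline; `simulate` writes just the
#' simulated cohort files; `validate` checks the configuration.  The config
#' file is JSON; recognised keys mirror [pipeline_config()] (`simulation`
#' and `match` given as plain objects of their constructor arguments).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
trajnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trajnet <run-all|simulate|validate> --config FILE",
    "[--seed S] [--out DIR]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$config)) { message(usage); return(invisible(1L)) }
  raw <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
  sim <- if (!is.null(raw$simulation))
    do.call(sim_config, raw$simulation)
  mc <- if (!is.null(raw$match)) do.call(match_config, raw$match)
        else match_config()
  cfg <- pipeline_config(
    input = raw$input, simulation = sim,
    direction_policy = raw$direction_policy %||% "bonferroni",
    alpha = raw$alpha %||% 0.05, match = mc,
    max_path_length = raw$max_path_length %||% 4L,
    top_k = raw$top_k %||% 10L,
    out_dir = opt$out %||% raw$out_dir %||% "trajnet_out",
    seed = as.integer(opt$seed %||% raw$seed %||% 1L),
    verbose = TRUE)

  status <- 0L
  switch(cmd,
    "validate" = {
      problems <- validate_config(cfg)
      if (length(problems)) { message(paste(problems, collapse = "\n"))
        status <- 1L } else message("configuration ok")
    },
    "simulate" = {
      if (is.null(cfg$simulation)) { message("no simulation config")
        status <- 1L }
      else {
        cfg$simulation$seed <- derive_seed(cfg$seed, 1L)
        res <- simulate_cohort(cfg$simulation)
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_cohort(res$cohort, file.path(cfg$out_dir, "events.csv"),
                     file.path(cfg$out_dir, "participants.csv"))
        message("cohort written to ", cfg$out_dir)
      }
    },
    "run-all" = {
      report <- run_pipeline(cfg)
      if (!is.na(report$failed_stage)) {
        message("failed at stage: ", report$failed_stage); status <- 1L
      } else {
        message(sprintf(
          "done: %s pairs tested, %s directed, %s edges selected, %s trajectories ranked",
          report$counts$pairs_tested %||% 0,
          report$counts$pairs_directed %||% 0,
          report$counts$edges_selected %||% 0,
          report$counts$trajectories_ranked %||% 0))
      }
    },
    { message("unknown subcommand: ", cmd); message(usage); status <- 1L }
  )
  invisible(status)
}
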