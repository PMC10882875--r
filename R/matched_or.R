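# Nested case-control construction with incidence-density sampling and a
# from-scratch conditional-logistic likelihood fitter with set-resampling
# bootstrap confidence intervals.
#
# For a directed pair d1 -> d2: cases are participants with *incident* d2
# (onset strictly after baseline); each case is matched on sex and baseline
# age (within a caliper) to controls drawn from the risk set at the case's
# d2 onset age ("index age") who were free of both d1 and d2 at baseline.
# Exposure is a d1 onset strictly before the index age.  With one case per
# set and a scalar binary exposure the conditional likelihood for a set
# with m members, k exposed and case exposure x_c is
#     exp(beta * x_c) / (k * exp(beta) + m - k),
# which the fitter maximizes by safeguarded Newton-Raphson over sets
# collapsed to their (m, k, x_c) sufficient patterns.

#' Matching and bootstrap configuration
#'
#' @param ratio Controls per case (default 3, the conventional 1:3 design).
#' @param age_caliper Half-width in years of the baseline-age matching
#'   window (default 2; use 0 for exact-age matching).
#' @param bootstrap_reps Number of set-resampling bootstrap replicates
#'   (default 1000).
#' @param ci_level Confidence level for the percentile interval
#'   (default 0.95).
#' @param seed Integer seed driving control sampling and the bootstrap.
#' @param min_controls Minimum eligible controls for a case's set to be
#'   retained (default 1).
#' @param reuse_controls Allow the same participant to serve as control in
#'   several sets (default `TRUE`, standard in incidence-density sampling;
#'   within one set controls are always distinct).
#' @return An object of class `match_config`.
#' @export
match_config <- function(ratio = 3L, age_caliper = 2, bootstrap_reps = 1000L,
                         ci_level = 0.95, seed = 1L, min_controls = 1L,
                         reuse_controls = TRUE) {
  if (!is_count(ratio) || ratio < 1)
    traj_error("trajnet_config_error", "ratio >= 1 required")
  if (!is_count(bootstrap_reps) || bootstrap_reps < 1)
    traj_error("trajnet_config_error", "bootstrap_reps >= 1 required")
  if (!(ci_level > 0 && ci_level < 1))
    traj_error("trajnet_config_error", "ci_level must lie in (0,1)")
  structure(list(ratio = as.integer(ratio), age_caliper = age_caliper,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ci_level = ci_level, seed = as.integer(seed),
                 min_controls = as.integer(min_controls),
                 reuse_controls = isTRUE(reuse_controls)),
            class = "match_config")
}

#' Build incidence-density matched case-control sets
#'
#' Cases are participants with incident `d2` (onset strictly after their
#' baseline age).  For each case, eligible controls are participants of the
#' same sex whose baseline age is within the caliper of the case's, who
#' were free of both `d1` and `d2` at baseline, still under observation at
#' the case's index age, and without a `d2` onset at or before the index
#' age.  Up to `ratio` controls are drawn uniformly at random (seeded).
#' Exposure, for every set member, is a `d1` onset strictly before the
#' index age.
#'
#' @param cohort A `traj_cohort`.
#' @param d1,d2 Exposure and outcome disease codes (direction `d1 -> d2`).
#' @param config A [match_config()].
#' @return Data frame of set members: `set_id`, `person_id`, `role`
#'   (`"case"`/`"control"`), `index_age`, `exposure`.  The number of cases
#'   dropped for lack of controls is attached as attribute
#'   `"dropped_cases"`.
#' @export
build_case_control <- function(cohort, d1, d2, config = match_config()) {
  stopifnot(inherits(cohort, "traj_cohort"),
            inherits(config, "match_config"))
  p <- cohort$participants
  om <- onset_matrix(cohort, c(d1, d2))
  o1 <- om[, 1]; o2 <- om[, 2]

  case_idx <- which(!is.na(o2) & o2 > p$entry_age)
  empty <- data.frame(set_id = integer(), person_id = character(),
                      role = character(), index_age = numeric(),
                      exposure = logical(), stringsAsFactors = FALSE)
  if (!length(case_idx)) {
    traj_warning(sprintf("no incident %s cases for pair %s -> %s",
                         d2, d1, d2))
    attr(empty, "dropped_cases") <- 0L
    return(empty)
  }
  # candidate controls must be free of both diseases at baseline; "at
  # baseline" means an onset strictly before the baseline age -- an onset
  # recorded in the entry year itself postdates the baseline interview
  # under year resolution (keeps exposure windows symmetric with cases)
  cand <- which((is.na(o1) | o1 >= p$entry_age) &
                  (is.na(o2) | o2 >= p$entry_age))
  # bucket candidates by sex and integer baseline age for fast lookup
  bucket_key <- paste(p$sex[cand], round(p$entry_age[cand]))
  buckets <- split(cand, bucket_key)

  set.seed(config$seed)
  case_idx <- case_idx[order(p$person_id[case_idx])]
  sets <- vector("list", length(case_idx))
  dropped <- 0L
  for (s in seq_along(case_idx)) {
    ci <- case_idx[s]
    index_age <- o2[ci]
    ages <- seq(round(p$entry_age[ci]) - config$age_caliper,
                round(p$entry_age[ci]) + config$age_caliper)
    pool <- unlist(buckets[paste(p$sex[ci], ages)], use.names = FALSE)
    pool <- pool[!is.na(pool) & pool != ci]
    if (length(pool)) {
      ok <- p$exit_age[pool] >= index_age &
        (is.na(o2[pool]) | o2[pool] > index_age) &
        abs(p$entry_age[pool] - p$entry_age[ci]) <= config$age_caliper
      pool <- pool[ok]
    }
    if (length(pool) < config$min_controls) { dropped <- dropped + 1L; next }
    ctrl <- if (length(pool) <= config$ratio) pool else
      pool[sample.int(length(pool), config$ratio)]
    members <- c(ci, ctrl)
    sets[[s]] <- data.frame(
      set_id = s, person_id = p$person_id[members],
      role = c("case", rep("control", length(ctrl))),
      index_age = unname(index_age),
      exposure = unname(!is.na(o1[members]) & o1[members] < index_age),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, sets[!vapply(sets, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  # renumber sets densely
  if (nrow(out)) out$set_id <- match(out$set_id, unique(out$set_id))
  attr(out, "dropped_cases") <- dropped
  out
}

# collapse matched sets to sufficient patterns (m = set size, k = number
# exposed, xc = case exposure) with multiplicities w
set_patterns <- function(sets) {
  stopifnot(all(c("set_id", "role", "exposure") %in% names(sets)))
  by_set <- split(seq_len(nrow(sets)), sets$set_id)
  m <- lengths(by_set)
  k <- vapply(by_set, function(i) sum(sets$exposure[i]), integer(1))
  xc <- vapply(by_set, function(i)
    sets$exposure[i][sets$role[i] == "case"][1], logical(1))
  key <- paste(m, k, xc)
  agg <- !duplicated(key)
  list(m = m[agg], k = k[agg], xc = as.numeric(xc[agg]),
       w = as.vector(table(key)[key[agg]]), n_sets = length(m))
}

clogit_loglik <- function(beta, pat, w = pat$w) {
  sum(w * (beta * pat$xc - log(pat$k * exp(beta) + pat$m - pat$k)))
}

# Newton-Raphson with step halving on the collapsed patterns
fit_clogit_patterns <- function(pat, w = pat$w, tol = 1e-8,
                                max_iter = 100L, beta_cap = 15) {
  informative <- pat$k > 0 & pat$k < pat$m & w > 0
  n_disc <- sum(w[informative])
  if (n_disc == 0)
    traj_error("trajnet_estimation_error",
               "no exposure-discordant matched sets; beta unidentifiable")
  xc_i <- pat$xc[informative]
  if (all(xc_i == 1) || all(xc_i == 0)) {
    return(list(beta = if (all(xc_i == 1)) Inf else -Inf, or = NA_real_,
                converged = FALSE, separation = TRUE, n_discordant = n_disc,
                loglik = NA_real_, n_iter = 0L))
  }
  beta <- 0; ll <- clogit_loglik(beta, pat, w)
  for (it in seq_len(max_iter)) {
    eb <- exp(beta)
    mu <- pat$k * eb / (pat$k * eb + pat$m - pat$k)
    score <- sum(w * (pat$xc - mu))
    info <- sum(w * pat$k * (pat$m - pat$k) * eb /
                  (pat$k * eb + pat$m - pat$k)^2)
    if (abs(score) < tol)
      return(list(beta = beta, or = exp(beta), converged = TRUE,
                  separation = FALSE, n_discordant = n_disc, loglik = ll,
                  n_iter = it))
    step <- score / info
    # step halving: never accept a decrease in the log-likelihood
    repeat {
      cand <- beta + step
      llc <- clogit_loglik(cand, pat, w)
      if (llc >= ll - 1e-12 || abs(step) < 1e-12) break
      step <- step / 2
    }
    beta <- cand; ll <- llc
    if (abs(beta) > beta_cap)
      return(list(beta = beta, or = NA_real_, converged = FALSE,
                  separation = TRUE, n_discordant = n_disc, loglik = ll,
                  n_iter = it))
  }
  list(beta = beta, or = exp(beta), converged = FALSE, separation = FALSE,
       n_discordant = n_disc, loglik = ll, n_iter = max_iter)
}

#' Conditional logistic regression on matched sets
#'
#' Maximizes the conditional log-likelihood
#' `sum over sets [beta * x_case - log(sum over members exp(beta * x))]`
#' for a scalar binary exposure by safeguarded Newton-Raphson (step halving;
#' convergence when the absolute score drops below `1e-8`).  Sets whose
#' members all share the same exposure contribute a constant and are
#' reported only in the diagnostics.  Complete separation (all discordant
#' sets pointing the same way, or the estimate escaping past `|beta| > 15`)
#' is flagged rather than returned as a spurious number.
#'
#' @param sets Data frame from [build_case_control()] (columns `set_id`,
#'   `role`, `exposure`).
#' @return A list: `beta`, `or`, `converged`, `separation`, `n_sets`,
#'   `n_discordant`, `loglik`, `n_iter`.
#' @export
clogit_fit <- function(sets) {
  pat <- set_patterns(sets)
  out <- fit_clogit_patterns(pat)
  out$n_sets <- pat$n_sets
  out
}

#' Set-resampling bootstrap confidence interval for the matched OR
#'
#' Resamples whole matched sets with replacement (`n_sets` draws per
#' replicate), refits the conditional-logistic model on each replicate, and
#' returns the percentile interval of the replicate ORs.  Replicates that
#' are unidentifiable, separated or non-convergent are dropped and counted;
#' more than 50% failures flags the interval unreliable.
#'
#' @param sets Data frame from [build_case_control()].
#' @param config A [match_config()] (`bootstrap_reps`, `ci_level`, `seed`).
#' @return A list: `ci_low`, `ci_high`, `mean_or` (mean replicate OR),
#'   `n_failed`, `n_reps`, `unreliable`, `reps` (the replicate ORs).
#' @export
bootstrap_ci <- function(sets, config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  pat <- set_patterns(sets)
  set.seed(config$seed)
  reps <- numeric(config$bootstrap_reps)
  failed <- 0L
  prob <- pat$w / sum(pat$w)
  for (r in seq_len(config$bootstrap_reps)) {
    w_r <- as.vector(stats::rmultinom(1L, pat$n_sets, prob))
    fit <- tryCatch(fit_clogit_patterns(pat, w = w_r),
                    trajnet_estimation_error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      failed <- failed + 1L
      reps[r] <- NA_real_
    } else reps[r] <- fit$or
  }
  ok <- reps[!is.na(reps)]
  if (!length(ok))
    traj_error("trajnet_estimation_error",
               "all bootstrap replicates failed")
  a <- (1 - config$ci_level) / 2
  ci <- stats::quantile(ok, c(a, 1 - a), type = 7, names = FALSE)
  list(ci_low = ci[1], ci_high = ci[2], mean_or = mean(ok),
       n_failed = failed, n_reps = config$bootstrap_reps,
       unreliable = failed > config$bootstrap_reps / 2, reps = reps)
}

#' Estimate matched odds ratios for every directed pair
#'
#' For each directed pair, builds the matched case-control sets, fits the
#' conditional-logistic model and computes the bootstrap interval.  A pair
#' is `selected` when its OR exceeds 1 and the confidence interval does not
#' contain 1.  Per-pair failures are recorded in the `note` column and do
#' not abort the remaining pairs.  Each pair gets its own seed derived from
#' `config$seed`, so results do not depend on execution order.
#'
#' @param cohort A `traj_cohort`.
#' @param directed Data frame with columns `source`, `target` (e.g. from
#'   [select_directed_pairs()]).
#' @param config A [match_config()].
#' @return Data frame, one row per pair, sorted by descending OR: `source`,
#'   `target`, `n_sets`, `n_discordant`, `beta`, `or`, `ci_low`, `ci_high`,
#'   `boot_mean_or`, `selected`, `note`.
#' @export
estimate_all_pairs <- function(cohort, directed, config = match_config()) {
  stopifnot(inherits(cohort, "traj_cohort"))
  rows <- lapply(seq_len(nrow(directed)), function(i) {
    cfg_i <- config
    # seed keyed to the pair identity, not its position in the list
    pair_h <- strtoi(substr(str_hash32(paste(directed$source[i],
                                          directed$target[i],
                                          sep = "->")), 1, 7), 16L)
    cfg_i$seed <- derive_seed(config$seed, pair_h)
    row <- data.frame(source = directed$source[i],
                      target = directed$target[i],
                      n_sets = 0L, n_discordant = 0L, beta = NA_real_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      boot_mean_or = NA_real_, selected = FALSE, note = "",
                      stringsAsFactors = FALSE)
    tryCatch({
      sets <- suppressWarnings(
        build_case_control(cohort, directed$source[i], directed$target[i],
                           cfg_i))
      if (!nrow(sets)) { row$note <- "no matched sets"; return(row) }
      fit <- clogit_fit(sets)
      row$n_sets <- fit$n_sets
      row$n_discordant <- fit$n_discordant
      row$beta <- fit$beta
      if (fit$separation) { row$note <- "separation"; return(row) }
      row$or <- fit$or
      ci <- bootstrap_ci(sets, cfg_i)
      row$ci_low <- ci$ci_low; row$ci_high <- ci$ci_high
      row$boot_mean_or <- ci$mean_or
      if (ci$unreliable) row$note <- "unreliable bootstrap"
      row$selected <- isTRUE(row$or > 1 && row$ci_low > 1)
      row
    }, trajnet_error = function(e) {
      row$note <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(), target = character(),
                      n_sets = integer(), n_discordant = integer(),
                      beta = numeric(), or = numeric(), ci_low = numeric(),
                      ci_high = numeric(), boot_mean_or = numeric(),
                      selected = logical(), note = character())
  out <- out[order(-ifelse(is.na(out$or), -Inf, out$or),
                   out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
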