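# Discrete-time multistate cohort simulator with planted directional
# dependencies.  Time runs in whole years of age, matching the
# year-resolution recall of onset ages in surveys like CHARLS; same-year
# onsets of two diseases are therefore a real, testable phenomenon rather
# than a tie-breaking artefact.

#' Simulation configuration
#'
#' Describes a synthetic ageing cohort: per-disease baseline onset hazards
#' on an age time-scale (constant or age-banded per-year onset
#' probabilities), a matrix of planted directional dependencies (hazard
#' ratios applied to a disease's hazard from the year *after* a predecessor
#' disease's onset), a survey-wave calendar with per-wave dropout, and
#' covariate/weight distributions.
#'
#' @param n_participants Cohort size (default 15000, the scale of a CHARLS
#'   analysis sample).
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   config and seed.
#' @param diseases Character vector of disease codes to simulate; defaults
#'   to the canonical fourteen.
#' @param baseline_hazards Named numeric vector of per-year onset
#'   probabilities (one per disease), or a named list whose elements are
#'   either scalars or `data.frame(age_from, rate)` step specifications for
#'   age-banded hazards.  Defaults echo the prevalence ordering seen in
#'   CHARLS (arthritis and hypertension commonest, cancer rarest).
#' @param dependency_hr `NULL`, or a data frame with columns `d1`, `d2`,
#'   `hr`: after `d1`'s onset year, `d2`'s per-year hazard is multiplied by
#'   `hr` (strictly subsequent years, so the planted direction is
#'   unambiguous).  Unlisted pairs have ratio 1.
#' @param entry_age_range Two integers; baseline ages are drawn uniformly on
#'   this closed range (default 45-75).
#' @param start_age Age at which the onset process starts: a number (default
#'   30, emulating recalled pre-baseline onsets) or `"entry"` to start each
#'   participant's process at their own baseline age (no prevalent disease).
#' @param waves Strictly increasing calendar years of the survey waves
#'   (default 2011, 2013, 2015, 2018).
#' @param dropout_per_wave Probability of dropping out at each follow-up
#'   wave; once dropped, a participant never returns, and their exit age is
#'   the age at the last attended wave (default 0.07).
#' @param female_prob,urban_prob,high_edu_prob,smoking_prob,drinking_prob
#'   Covariate Bernoulli probabilities (defaults match published CHARLS
#'   weighted descriptives).
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param max_age Hard cap on simulated age (default 100).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 15000,
                       seed = 1L,
                       diseases = NULL,
                       baseline_hazards = NULL,
                       dependency_hr = NULL,
                       entry_age_range = c(45, 75),
                       start_age = 30,
                       waves = c(2011, 2013, 2015, 2018),
                       dropout_per_wave = 0.07,
                       female_prob = 0.5207,
                       urban_prob = 0.4706,
                       high_edu_prob = 0.1433,
                       smoking_prob = 0.3043,
                       drinking_prob = 0.3318,
                       weight_meanlog = 0,
                       weight_sdlog = 0.5,
                       max_age = 100) {
  if (is.null(baseline_hazards)) {
    diseases <- diseases %||% .diseases
    baseline_hazards <- .default_hazards[diseases]
  } else {
    diseases <- diseases %||% names(baseline_hazards)
  }
  cfg <- structure(list(
    n_participants = n_participants, seed = as.integer(seed),
    diseases = diseases, baseline_hazards = baseline_hazards,
    dependency_hr = dependency_hr, entry_age_range = entry_age_range,
    start_age = start_age, waves = waves,
    dropout_per_wave = dropout_per_wave, female_prob = female_prob,
    urban_prob = urban_prob, high_edu_prob = high_edu_prob,
    smoking_prob = smoking_prob, drinking_prob = drinking_prob,
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    max_age = max_age), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# plausible per-year onset probabilities; chosen once so that lifetime
# prevalence over a few decades of exposure mirrors the ordering of CHARLS
# weighted prevalences (arthritis ~40%, hypertension ~29%, ... cancer ~1%)
.default_hazards <- c(
  hypertension = 0.0100, dyslipidemia = 0.0045, diabetes = 0.0025,
  cancer = 0.0005, chronic_lung = 0.0050, liver = 0.0020, heart = 0.0050,
  stroke = 0.0015, kidney = 0.0030, digestive = 0.0090, emp = 0.0010,
  mrd = 0.0008, arthritis = 0.0140, asthma = 0.0018)

validate_sim_config <- function(cfg) {
  problems <- character()
  if (!is_count(cfg$n_participants))
    problems <- c(problems, "n_participants must be a non-negative integer")
  if (is.null(names(cfg$baseline_hazards)) ||
      !setequal(names(cfg$baseline_hazards), cfg$diseases))
    problems <- c(problems,
                  "baseline_hazards must be named by the simulated diseases")
  rates <- unlist(lapply(cfg$baseline_hazards, function(h)
    if (is.data.frame(h)) h$rate else h))
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 1))
    problems <- c(problems, "per-year onset probabilities must lie in [0,1)")
  if (!is.null(cfg$dependency_hr)) {
    d <- cfg$dependency_hr
    if (!all(c("d1", "d2", "hr") %in% names(d)))
      problems <- c(problems, "dependency_hr needs columns d1, d2, hr")
    else {
      if (any(!is.finite(d$hr)) || any(d$hr <= 0))
        problems <- c(problems, "hazard ratios must be positive")
      if (any(!d$d1 %in% cfg$diseases) || any(!d$d2 %in% cfg$diseases))
        problems <- c(problems, "dependency_hr names unknown diseases")
      if (any(d$d1 == d$d2))
        problems <- c(problems, "self-dependencies are not allowed")
    }
  }
  if (any(diff(cfg$waves) <= 0))
    problems <- c(problems, "waves must be strictly increasing")
  if (cfg$dropout_per_wave < 0 || cfg$dropout_per_wave >= 1)
    problems <- c(problems, "dropout_per_wave must lie in [0,1)")
  if (!identical(cfg$start_age, "entry") && !is.numeric(cfg$start_age))
    problems <- c(problems, "start_age must be numeric or \"entry\"")
  if (length(problems))
    traj_error("trajnet_config_error",
               paste(problems, collapse = "; "), data = problems)
  invisible(cfg)
}

hazard_at <- function(spec, age) {
  if (is.data.frame(spec)) {
    i <- findInterval(age, spec$age_from)
    if (i < 1L) 0 else spec$rate[i]
  } else as.numeric(spec)
}

#' Simulate a cohort with known ground truth
#'
#' Runs a yearly discrete-time multistate simulation: each year of age, each
#' not-yet-onset disease fires with probability
#' `baseline(age) * prod(hazard ratios of already-onset predecessors)`.
#' A dependency takes effect from the year *after* the predecessor's onset,
#' so planted directions are strict.  Survey-wave attendance with dropout
#' converts to right censoring at the age of the last attended wave; onsets
#' are tagged with the first attended wave at or after the onset calendar
#' year (pre-baseline onsets report at baseline, emulating recall).
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a `traj_cohort`) and
#'   `ground_truth` (list: `pairs`, the planted directed pairs with true
#'   hazard ratios != 1; `baseline_hazards`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  dis <- config$diseases
  k <- length(dis)
  waves <- config$waves

  gt_pairs <- config$dependency_hr
  gt_pairs <- if (is.null(gt_pairs)) {
    data.frame(d1 = character(), d2 = character(), hr = numeric())
  } else gt_pairs[gt_pairs$hr != 1, c("d1", "d2", "hr"), drop = FALSE]
  ground_truth <- list(pairs = gt_pairs,
                       baseline_hazards = config$baseline_hazards)

  if (n == 0L) {
    empty <- new_cohort(
      data.frame(person_id = character(), sex = character(),
                 birth_year = integer(), education = character(),
                 residence = character(), smoking = character(),
                 drinking = character(), weight = numeric(),
                 entry_age = numeric(), exit_age = numeric()),
      diseases = dis)
    return(list(cohort = empty, ground_truth = ground_truth))
  }

  person_id <- sprintf("p%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_prob, "female", "male")
  entry_age <- floor(stats::runif(n, config$entry_age_range[1],
                                  config$entry_age_range[2] + 1))
  entry_age <- pmin(entry_age, config$entry_age_range[2])
  birth_year <- waves[1] - entry_age
  education <- ifelse(stats::runif(n) < config$high_edu_prob, "high", "low")
  residence <- ifelse(stats::runif(n) < config$urban_prob, "urban", "rural")
  smoking <- ifelse(stats::runif(n) < config$smoking_prob, "yes", "no")
  drinking <- ifelse(stats::runif(n) < config$drinking_prob, "yes", "no")
  weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)

  # wave attendance: baseline always; monotone dropout afterwards
  attended <- matrix(TRUE, n, length(waves))
  for (w in seq_along(waves)[-1]) {
    attended[, w] <- attended[, w - 1L] &
      stats::runif(n) >= config$dropout_per_wave
  }
  last_wave_year <- waves[max.col(attended, ties.method = "last")]
  exit_age <- pmin(entry_age + (last_wave_year - waves[1]), config$max_age)

  start <- if (identical(config$start_age, "entry")) entry_age
           else pmax(0, pmin(as.numeric(config$start_age), entry_age))

  logHR <- matrix(0, k, k, dimnames = list(dis, dis))
  if (nrow(gt_pairs))
    logHR[cbind(gt_pairs$d1, gt_pairs$d2)] <- log(gt_pairs$hr)
  has_dep <- any(logHR != 0)

  onset <- matrix(NA_real_, n, k, dimnames = list(NULL, dis))
  ages <- seq(min(start), max(exit_age))
  for (a in ages) {
    at_risk <- is.na(onset) & (a >= start) & (a <= exit_age)
    if (!any(at_risk)) next
    base_a <- vapply(dis, function(d)
      hazard_at(config$baseline_hazards[[d]], a), numeric(1))
    p <- matrix(base_a, n, k, byrow = TRUE)
    if (has_dep) {
      pred <- (!is.na(onset)) & onset < a
      p <- p * exp(pred %*% logHR)
    }
    if (any(p[at_risk] >= 1))
      traj_error("trajnet_config_error", sprintf(
        "effective per-year onset probability >= 1 at age %d", a))
    fire <- at_risk & (matrix(stats::runif(n * k), n, k) < p)
    onset[fire] <- a
  }

  idx <- which(!is.na(onset), arr.ind = TRUE)
  if (nrow(idx)) {
    ev_person <- person_id[idx[, 1]]
    ev_onset <- onset[idx]
    onset_year <- birth_year[idx[, 1]] + ev_onset
    # first attended wave at or after the onset year; recall places
    # pre-baseline onsets at the baseline wave
    report_wave <- vapply(seq_len(nrow(idx)), function(i) {
      ws <- waves[attended[idx[i, 1], ]]
      later <- ws[ws >= onset_year[i]]
      if (length(later)) later[1] else ws[length(ws)]
    }, numeric(1))
    events <- data.frame(person_id = ev_person, disease = dis[idx[, 2]],
                         onset_age = ev_onset,
                         report_wave = as.integer(report_wave),
                         confirmed = TRUE, stringsAsFactors = FALSE)
    events <- events[order(events$person_id, events$disease), , drop = FALSE]
    rownames(events) <- NULL
  } else events <- NULL

  participants <- data.frame(
    person_id = person_id, sex = sex, birth_year = as.integer(birth_year),
    education = education, residence = residence, smoking = smoking,
    drinking = drinking, weight = weight, entry_age = entry_age,
    exit_age = exit_age, stringsAsFactors = FALSE)

  cohort <- new_cohort(participants, events,
                       provenance = sprintf(
                         "simulated: n=%d seed=%d diseases=%d", n,
                         config$seed, k),
                       min_entry_age = min(45, config$entry_age_range[1]),
                       diseases = dis)
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Simulate a null cohort (no planted dependencies)
#'
#' Convenience wrapper: strips every dependency from the configuration and
#' returns just the cohort.  Under the null, the forward/backward ordering
#' counts of any two identically-hazarded diseases are binomial around 1/2.
#'
#' @param config A [sim_config()].
#' @return A `traj_cohort`.
#' @export
null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$dependency_hr <- NULL
  simulate_cohort(config)$cohort
}
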