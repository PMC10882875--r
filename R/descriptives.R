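# Survey-weighted descriptives and age-scale Kaplan-Meier cumulative
# incidence.  The product-limit computation itself is delegated to the
# survival package; this layer owns the risk-set conventions (left
# truncation at entry vs prevalent recalled onsets) and the output contract.

#' Per-disease summary of first-onset ages
#'
#' Median and interquartile range of the age at first chronic disease, by
#' disease.  Quantiles use linear interpolation between order statistics
#' (R's default type-7 convention).
#'
#' @param first Data frame from [first_onsets()].
#' @return Data frame with columns `disease`, `n`, `q1`, `median`, `q3`.
#'   Diseases with zero records are omitted; their codes are attached as the
#'   `"omitted"` attribute.
#' @export
onset_age_summary <- function(first) {
  stopifnot(is.data.frame(first),
            all(c("disease", "onset_age") %in% names(first)))
  split_ages <- split(first$onset_age, first$disease)
  rows <- lapply(names(split_ages), function(d) {
    q <- stats::quantile(split_ages[[d]], c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(disease = d, n = length(split_ages[[d]]), q1 = q[1],
               median = q[2], q3 = q[3], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), n = integer(), q1 = numeric(),
               median = numeric(), q3 = numeric())
  attr(out, "omitted") <- setdiff(unique(first$disease), out$disease)
  out
}

#' Kaplan-Meier cumulative incidence on an age time-scale
#'
#' One minus the product-limit survival estimate for a single disease, with
#' age as the time axis.  Two risk-set conventions are provided:
#'
#' * `"prevalent"` (default): recalled pre-baseline onsets count as events
#'   at their reported age and everyone is at risk from age 0 — the natural
#'   reading when onset ages are self-reported recall data.
#' * `"left"`: participants enter the risk set at their baseline age
#'   (left truncation); participants whose onset predates entry are excluded
#'   since they were never at risk under observation.
#'
#' @param cohort A `traj_cohort`.
#' @param disease A disease code.
#' @param age_group `"overall"`, `"45-64"` or `">=65"`, selecting
#'   participants by baseline age.
#' @param truncation `"prevalent"` or `"left"` (see above).
#' @return An object of class `km_curve`: a data frame of step points with
#'   columns `age`, `cum_inc`, `n_risk`, `n_event`.
#' @export
km_cumulative_incidence <- function(cohort, disease,
                                    age_group = c("overall", "45-64",
                                                  ">=65"),
                                    truncation = c("prevalent", "left")) {
  stopifnot(inherits(cohort, "traj_cohort"))
  age_group <- match.arg(age_group)
  truncation <- match.arg(truncation)
  p <- cohort$participants
  p <- switch(age_group,
              "overall" = p,
              "45-64" = p[p$entry_age <= 64, , drop = FALSE],
              ">=65" = p[p$entry_age >= 65, , drop = FALSE])
  if (nrow(p) == 0L)
    traj_error("trajnet_estimation_error",
               sprintf("no participants in age group %s", age_group))
  ev <- cohort$events[cohort$events$disease == disease, , drop = FALSE]
  onset <- ev$onset_age[match(p$person_id, ev$person_id)]
  event <- !is.na(onset)
  time <- ifelse(event, onset, p$exit_age)

  if (truncation == "left") {
    # prevalent onsets were never at risk under observation; participants
    # censored at entry contribute no risk time either
    keep <- !(event & onset <= p$entry_age) & time > p$entry_age
    entry <- p$entry_age[keep]; time <- time[keep]; event <- event[keep]
    if (!length(time))
      traj_error("trajnet_estimation_error", "empty risk set")
    fit <- survival::survfit(survival::Surv(entry, time, event) ~ 1)
  } else {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  }
  out <- data.frame(age = fit$time, cum_inc = 1 - fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  if (any(out$n_event > 0 & out$n_risk <= 0))
    traj_error("trajnet_estimation_error", sprintf(
      "empty risk set at event age %s",
      out$age[which(out$n_event > 0 & out$n_risk <= 0)[1]]))
  structure(out, class = c("km_curve", "data.frame"),
            disease = disease, age_group = age_group,
            truncation = truncation)
}

#' Per-disease histogram of onset ages
#'
#' Counts of onsets by single year of age; counts sum to the number of
#' events per disease.
#'
#' @param cohort A `traj_cohort`.
#' @return Data frame with columns `disease`, `onset_age`, `count`.
#' @export
onset_age_histogram <- function(cohort) {
  stopifnot(inherits(cohort, "traj_cohort"))
  ev <- cohort$events
  if (nrow(ev) == 0L)
    return(data.frame(disease = character(), onset_age = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(disease = ev$disease,
                             onset_age = ev$onset_age),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(disease = tab$disease,
                    onset_age = as.numeric(tab$onset_age),
                    count = tab$Freq, stringsAsFactors = FALSE)
  out <- out[order(out$disease, out$onset_age), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Survey-weighted prevalence
#'
#' Weighted percentage of participants positive for a disease, or in a
#' given level of a covariate: `100 * sum(w[positive]) / sum(w)`.
#'
#' @param cohort A `traj_cohort`.
#' @param what A disease code, or the name of a participant covariate column
#'   (e.g. `"sex"`).
#' @param level For covariates, the level whose share is reported (e.g.
#'   `"female"`); ignored for diseases.
#' @param weighted Use survey weights (default `TRUE`).
#' @return A percentage in `[0, 100]`.
#' @export
weighted_prevalence <- function(cohort, what, level = NULL,
                                weighted = TRUE) {
  stopifnot(inherits(cohort, "traj_cohort"))
  p <- cohort$participants
  w <- if (weighted) p$weight else rep(1, nrow(p))
  if (!length(w) || sum(w) <= 0)
    traj_error("trajnet_validation_error", "total weight is zero")
  if (what %in% names(p) && !what %in% .diseases) {
    if (is.null(level))
      traj_error("trajnet_validation_error",
                 sprintf("level required for covariate '%s'", what))
    positive <- p[[what]] == level & !is.na(p[[what]])
  } else {
    has <- unique(cohort$events$person_id[cohort$events$disease == what])
    positive <- p$person_id %in% has
  }
  100 * sum(w[positive]) / sum(w)
}
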