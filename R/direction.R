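# Pairwise temporal ordering of diseases and the exact binomial direction
# test.  For a pair (d1, d2), participants who developed both diseases in
# distinct years split into N1 (d1 strictly first) and N2 (d2 strictly
# first); same-year onsets are "simultaneous" and excluded from the test.
# Under no directional dependence, N1 ~ Binomial(N1 + N2, 1/2).

#' Enumerate unordered disease pairs
#'
#' All k(k-1)/2 unordered pairs of distinct disease codes, in canonical
#' order (pairs sorted within and across rows).
#'
#' @param diseases Character vector of distinct disease codes.
#' @return Data frame with columns `d1`, `d2`.
#' @export
enumerate_pairs <- function(diseases) {
  if (anyDuplicated(diseases))
    traj_error("trajnet_validation_error", "duplicate disease codes")
  diseases <- sort(diseases)
  if (length(diseases) < 2L)
    return(data.frame(d1 = character(), d2 = character()))
  m <- utils::combn(diseases, 2L)
  data.frame(d1 = m[1, ], d2 = m[2, ], stringsAsFactors = FALSE)
}

# wide person x disease matrix of onset ages (NA where never diagnosed);
# the workhorse lookup for direction counting and trajectory statistics
onset_matrix <- function(cohort, diseases = NULL) {
  p_ids <- cohort$participants$person_id
  diseases <- diseases %||% sort(unique(cohort$events$disease))
  m <- matrix(NA_real_, length(p_ids), length(diseases),
              dimnames = list(p_ids, diseases))
  ev <- cohort$events[cohort$events$disease %in% diseases, , drop = FALSE]
  if (nrow(ev))
    m[cbind(match(ev$person_id, p_ids),
            match(ev$disease, diseases))] <- ev$onset_age
  m
}

#' Count temporal orderings for one disease pair
#'
#' Among participants with onsets of both diseases: `n1` developed `d1`
#' strictly (by at least a year) before `d2`, `n2` the reverse, and `n_sim`
#' had both in the same year.  `n = n1 + n2` excludes the simultaneous
#' onsets.
#'
#' @param cohort A `traj_cohort`.
#' @param d1,d2 Disease codes.
#' @return A list with elements `d1`, `d2`, `n1`, `n2`, `n_sim`, `n`.
#' @export
count_directions <- function(cohort, d1, d2) {
  stopifnot(inherits(cohort, "traj_cohort"))
  om <- onset_matrix(cohort, c(d1, d2))
  count_directions_ages(om[, 1], om[, 2], d1, d2)
}

count_directions_ages <- function(a1, a2, d1, d2) {
  both <- !is.na(a1) & !is.na(a2)
  n1 <- sum(both & a1 < a2)
  n2 <- sum(both & a2 < a1)
  n_sim <- sum(both & a1 == a2)
  list(d1 = d1, d2 = d2, n1 = n1, n2 = n2, n_sim = n_sim, n = n1 + n2)
}

# two-sided exact binomial p-value for the observed split under p0 = 1/2;
# by symmetry of the null this equals the sum of both extreme tails
binomial_direction_p <- function(n1, n2) {
  n <- n1 + n2
  if (n == 0L) return(NA_real_)
  hi <- max(n1, n2)
  min(1, 2 * stats::pbinom(hi - 1L, n, 0.5, lower.tail = FALSE))
}

#' Exact binomial test of pair direction
#'
#' Tests whether the ordering split (`n1` vs `n2`) of a disease pair is
#' compatible with a fair coin; the majority side defines the candidate
#' direction.  With zero usable orderings the pair is flagged untestable
#' and never significant.
#'
#' @param counts Output of [count_directions()].
#' @param threshold Significance cutoff applied to the two-sided p-value.
#' @return A one-row data frame: `source`, `target`, `n1`, `n2`, `n_sim`,
#'   `n`, `p_value`, `threshold`, `significant`, `testable`.
#' @export
exact_binomial_direction_test <- function(counts, threshold = 0.05) {
  with(counts, {
    p <- binomial_direction_p(n1, n2)
    forward <- n1 >= n2   # ties keep canonical order, never significant
    data.frame(
      source = if (forward) d1 else d2,
      target = if (forward) d2 else d1,
      n1 = n1, n2 = n2, n_sim = n_sim, n = n,
      p_value = p, threshold = threshold,
      significant = !is.na(p) && p < threshold && n1 != n2,
      testable = n > 0L, stringsAsFactors = FALSE)
  })
}

#' Direction-test every disease pair in a cohort
#'
#' Runs [count_directions()] and [exact_binomial_direction_test()] over all
#' unordered pairs of the given diseases.  Three threshold policies are
#' offered because "0.05 corrected" is ambiguous in parts of the
#' literature:
#'
#' * `"bonferroni"` (default): `alpha / number of pairs tested` — the
#'   family-wise reading.
#' * `"per_pair_n"`: `alpha / n` with `n` the pair's own usable ordering
#'   count — a per-pair adaptive cutoff used by some trajectory studies.
#' * `"fixed"`: `alpha` as given, uncorrected.
#'
#' @param cohort A `traj_cohort`.
#' @param diseases Disease codes to test (default: all present in the
#'   cohort's events).
#' @param policy Threshold policy (see above).
#' @param alpha Base significance level (default 0.05).
#' @return Data frame, one row per unordered pair, columns as in
#'   [exact_binomial_direction_test()].
#' @export
direction_test_all <- function(cohort, diseases = NULL,
                               policy = c("bonferroni", "per_pair_n",
                                          "fixed"),
                               alpha = 0.05) {
  stopifnot(inherits(cohort, "traj_cohort"))
  policy <- match.arg(policy)
  diseases <- diseases %||% sort(unique(cohort$events$disease))
  pairs <- enumerate_pairs(diseases)
  om <- onset_matrix(cohort, diseases)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cnt <- count_directions_ages(om[, pairs$d1[i]], om[, pairs$d2[i]],
                                 pairs$d1[i], pairs$d2[i])
    thr <- switch(policy,
                  bonferroni = alpha / nrow(pairs),
                  per_pair_n = if (cnt$n > 0) alpha / cnt$n else 0,
                  fixed = alpha)
    exact_binomial_direction_test(cnt, thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "policy") <- policy
  attr(out, "alpha") <- alpha
  out
}

#' Keep only significantly directed pairs
#'
#' @param results Data frame from [direction_test_all()].
#' @return The significant rows, in canonical (source, target) order.
#' @export
select_directed_pairs <- function(results) {
  out <- results[results$significant %in% TRUE, , drop = FALSE]
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
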