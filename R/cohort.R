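# Cohort data model: participants + year-resolution disease-onset events.
#
# A cohort is a plain list with class "traj_cohort":
#   participants: data.frame(person_id, sex, birth_year, education, residence,
#                            smoking, drinking, weight, entry_age, exit_age)
#   events:       data.frame(person_id, disease, onset_age, report_wave,
#                            confirmed)
#   provenance:   character vector, an append-only audit log

.participant_cols <- c("person_id", "sex", "birth_year", "education",
                       "residence", "smoking", "drinking", "weight",
                       "entry_age", "exit_age")
.event_cols <- c("person_id", "disease", "onset_age", "report_wave",
                 "confirmed")
.demog_cols <- c("sex", "birth_year", "education", "residence",
                 "smoking", "drinking")

#' Construct a validated cohort
#'
#' Bundles a participant table and an onset-event table into a cohort object,
#' enforcing the structural invariants of the data model: unique
#' `person_id`s, referential integrity of events, non-negative onset ages not
#' exceeding the participant's exit age, positive survey weights,
#' `exit_age >= entry_age`, and at most one retained event per
#' (person, disease).
#'
#' @param participants Data frame with columns `person_id`, `sex`,
#'   `birth_year`, `education`, `residence`, `smoking`, `drinking`, `weight`,
#'   `entry_age`, `exit_age`.  Demographic fields may be `NA` (such rows are
#'   removed later by [apply_exclusions()]); `weight`, `entry_age` and
#'   `exit_age` may not.
#' @param events Data frame with columns `person_id`, `disease`, `onset_age`,
#'   `report_wave`, `confirmed`.
#' @param provenance Character vector of free-text audit entries.
#' @param min_entry_age Admissible floor for `entry_age` (default 45, the
#'   usual eligibility threshold for ageing cohorts such as CHARLS).
#' @param diseases Allowed disease codes; defaults to the canonical
#'   fourteen-token vocabulary (see [disease_vocabulary()]).  Pass other
#'   codes for simulated cohorts that use a reduced disease set.
#' @return An object of class `traj_cohort`.
#' @export
new_cohort <- function(participants, events = NULL, provenance = character(),
                       min_entry_age = 45, diseases = NULL) {
  if (is.null(events)) {
    events <- data.frame(person_id = character(), disease = character(),
                         onset_age = numeric(), report_wave = integer(),
                         confirmed = logical(), stringsAsFactors = FALSE)
  }
  missing_p <- setdiff(.participant_cols, names(participants))
  missing_e <- setdiff(.event_cols, names(events))
  if (length(missing_p) || length(missing_e)) {
    traj_error("trajnet_schema_error", sprintf(
      "missing required columns: %s",
      paste(c(missing_p, missing_e), collapse = ", ")))
  }
  participants <- participants[, .participant_cols, drop = FALSE]
  events <- events[, .event_cols, drop = FALSE]
  participants$person_id <- as.character(participants$person_id)
  events$person_id <- as.character(events$person_id)
  events$disease <- as.character(events$disease)

  dup <- participants$person_id[duplicated(participants$person_id)]
  if (length(dup)) {
    traj_error("trajnet_integrity_error", sprintf(
      "duplicate person_id in participants: %s",
      paste(unique(dup), collapse = ", ")), data = unique(dup))
  }

  problems <- validate_cohort_rows(participants, events,
                                   min_entry_age = min_entry_age,
                                   diseases = diseases)
  if (nrow(problems$integrity)) {
    traj_error("trajnet_integrity_error", sprintf(
      "%d integrity problem(s), e.g.: %s", nrow(problems$integrity),
      problems$integrity$message[1]), data = problems$integrity)
  }
  if (nrow(problems$validation)) {
    traj_error("trajnet_validation_error", sprintf(
      "%d invalid row(s), e.g.: %s", nrow(problems$validation),
      problems$validation$message[1]), data = problems$validation)
  }

  structure(list(participants = participants, events = events,
                 provenance = provenance),
            class = "traj_cohort")
}

# row-level checks; returns data frames describing every offending row so
# malformed input is reported in full rather than silently dropped
validate_cohort_rows <- function(participants, events, min_entry_age = 45,
                                 diseases = NULL) {
  val <- list(); int <- list()
  bad <- function(table, row, message)
    data.frame(table = table, row = row, message = message,
               stringsAsFactors = FALSE)

  w <- which(!is.finite(participants$weight) | participants$weight <= 0)
  if (length(w)) val[[length(val) + 1L]] <- bad("participants", w, sprintf(
    "weight must be positive (person %s)", participants$person_id[w]))
  w <- which(is.na(participants$entry_age) | is.na(participants$exit_age) |
               participants$exit_age < participants$entry_age)
  if (length(w)) val[[length(val) + 1L]] <- bad("participants", w, sprintf(
    "exit_age must be >= entry_age (person %s)", participants$person_id[w]))
  w <- which(!is.na(participants$entry_age) &
               participants$entry_age < min_entry_age)
  if (length(w)) val[[length(val) + 1L]] <- bad("participants", w, sprintf(
    "entry_age below admissible floor %s (person %s)", min_entry_age,
    participants$person_id[w]))

  if (nrow(events)) {
    unknown <- which(!events$person_id %in% participants$person_id)
    if (length(unknown)) int[[length(int) + 1L]] <- bad("events", unknown,
      sprintf("event references unknown person_id '%s'",
              events$person_id[unknown]))
    dupe <- which(duplicated(events[, c("person_id", "disease")]))
    if (length(dupe)) int[[length(int) + 1L]] <- bad("events", dupe, sprintf(
      "more than one event for (person %s, disease %s)",
      events$person_id[dupe], events$disease[dupe]))
    w <- which(is.na(events$onset_age) | events$onset_age < 0)
    if (length(w)) val[[length(val) + 1L]] <- bad("events", w, sprintf(
      "onset_age must be a non-negative year count (person %s)",
      events$person_id[w]))
    vocab <- diseases %||% .diseases
    w <- which(!events$disease %in% vocab)
    if (length(w)) val[[length(val) + 1L]] <- bad("events", w, sprintf(
      "unknown disease code '%s'", events$disease[w]))
    exit_of <- participants$exit_age[match(events$person_id,
                                           participants$person_id)]
    w <- which(!is.na(events$onset_age) & !is.na(exit_of) &
                 events$onset_age > exit_of)
    if (length(w)) val[[length(val) + 1L]] <- bad("events", w, sprintf(
      "onset_age after participant exit (person %s, disease %s)",
      events$person_id[w], events$disease[w]))
  }
  empty <- data.frame(table = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE)
  list(validation = if (length(val)) do.call(rbind, val) else empty,
       integrity = if (length(int)) do.call(rbind, int) else empty)
}

#' @export
print.traj_cohort <- function(x, ...) {
  cat(sprintf("<traj_cohort> %d participants, %d onset events, %d diseases\n",
              nrow(x$participants), nrow(x$events),
              length(unique(x$events$disease))))
  if (length(x$provenance))
    cat("provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' Loads an onset-event table and a participant table (documented column
#' schemas; see [new_cohort()]) and returns a validated cohort.  Structural
#' problems raise classed errors (`trajnet_schema_error`,
#' `trajnet_integrity_error`, `trajnet_validation_error`); the full set of
#' offending rows travels in the condition's `data` field so nothing is
#' silently dropped.
#'
#' @param events_path Path to the events file.
#' @param participants_path Path to the participants file.
#' @param sep Field delimiter (default comma).
#' @inheritParams new_cohort
#' @return A `traj_cohort`.
#' @export
read_cohort <- function(events_path, participants_path, sep = ",",
                        min_entry_age = 45, diseases = NULL) {
  participants <- utils::read.table(participants_path, header = TRUE,
                                    sep = sep, stringsAsFactors = FALSE,
                                    comment.char = "#")
  events <- utils::read.table(events_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, comment.char = "#")
  if ("confirmed" %in% names(events))
    events$confirmed <- as.logical(events$confirmed)
  new_cohort(participants, events,
             provenance = sprintf("read from %s + %s",
                                  basename(events_path),
                                  basename(participants_path)),
             min_entry_age = min_entry_age, diseases = diseases)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` is the
#' identity on valid cohorts.
#'
#' @param cohort A `traj_cohort`.
#' @inheritParams read_cohort
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, events_path, participants_path, sep = ",") {
  stopifnot(inherits(cohort, "traj_cohort"))
  utils::write.table(cohort$events, events_path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$participants, participants_path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(c(events = events_path, participants = participants_path))
}

#' Apply cohort exclusion rules
#'
#' Removes participants who contributed no follow-up observation (only the
#' baseline wave: `exit_age == entry_age`) and participants with missing
#' demographic fields, in that fixed order, so a participant failing both
#' rules is counted once under the first.  Events of removed participants
#' are removed with them.
#'
#' @param cohort A `traj_cohort`.
#' @param rules Named list of flags: `no_followup`, `missing_demog`
#'   (both default `TRUE`).
#' @return A list with elements `cohort` (the filtered cohort) and `log`
#'   (named counts: `input`, `no_followup`, `missing_demog`, `retained`).
#'   `retained + no_followup + missing_demog == input` always holds.
#' @export
apply_exclusions <- function(cohort,
                             rules = list(no_followup = TRUE,
                                          missing_demog = TRUE)) {
  stopifnot(inherits(cohort, "traj_cohort"))
  p <- cohort$participants
  n_in <- nrow(p)
  log <- c(input = n_in, no_followup = 0L, missing_demog = 0L,
           retained = 0L)

  if (isTRUE(rules$no_followup)) {
    drop <- !is.na(p$exit_age) & !is.na(p$entry_age) &
      p$exit_age <= p$entry_age
    log["no_followup"] <- sum(drop)
    p <- p[!drop, , drop = FALSE]
  }
  if (isTRUE(rules$missing_demog)) {
    drop <- Reduce(`|`, lapply(p[.demog_cols], function(col)
      is.na(col) | (is.character(col) & !nzchar(col))))
    log["missing_demog"] <- sum(drop)
    p <- p[!drop, , drop = FALSE]
  }
  log["retained"] <- nrow(p)
  if (nrow(p) == 0L && n_in > 0L)
    traj_warning("all participants excluded; cohort is empty")

  ev <- cohort$events[cohort$events$person_id %in% p$person_id, ,
                      drop = FALSE]
  out <- structure(list(
    participants = p, events = ev,
    provenance = c(cohort$provenance, sprintf(
      "exclusions: input=%d no_followup=%d missing_demog=%d retained=%d",
      log["input"], log["no_followup"], log["missing_demog"],
      log["retained"]))), class = "traj_cohort")
  list(cohort = out, log = as.list(log))
}

#' Resolve multi-wave disease reports into one event per person and disease
#'
#' Longitudinal surveys re-ask about previously reported diagnoses, so one
#' (person, disease) can accumulate several per-wave statements.  The
#' resolution rule is: process statements in wave order; a statement with
#' `accurate = TRUE` affirms the disease (a non-`NA` `onset_age` sets or
#' re-states the onset, `NA` confirms the standing one); a statement with
#' `accurate = FALSE` declares the previous report wrong — with a
#' replacement `onset_age` it corrects the onset, with `NA` it retracts the
#' event entirely.  The most recent statement is authoritative.
#'
#' @param reports Data frame with columns `person_id`, `disease`,
#'   `report_wave`, `onset_age`, `accurate` (logical).
#' @return Data frame of resolved events (`person_id`, `disease`,
#'   `onset_age`, `report_wave`, `confirmed`), where `confirmed` marks events
#'   affirmed in more than one wave and `report_wave` is the wave whose
#'   statement fixed the final onset age.
#' @export
resolve_recall <- function(reports) {
  required <- c("person_id", "disease", "report_wave", "onset_age",
                "accurate")
  missing <- setdiff(required, names(reports))
  if (length(missing))
    traj_error("trajnet_schema_error",
               sprintf("reports lack column(s): %s",
                       paste(missing, collapse = ", ")))
  if (nrow(reports) == 0L)
    return(data.frame(person_id = character(), disease = character(),
                      onset_age = numeric(), report_wave = integer(),
                      confirmed = logical(), stringsAsFactors = FALSE))

  key3 <- paste(reports$person_id, reports$disease, reports$report_wave,
                sep = "\r")
  if (anyDuplicated(key3)) {
    d <- reports[key3 %in% key3[duplicated(key3)], , drop = FALSE]
    # identical duplicates are tolerated; conflicting ones are not
    sig <- paste(key3, d$onset_age, d$accurate)[key3 %in%
                                                  key3[duplicated(key3)]]
    if (length(unique(sig)) != length(unique(key3[key3 %in%
                                                  key3[duplicated(key3)]])))
      traj_error("trajnet_integrity_error",
                 "conflicting duplicate reports within one wave",
                 data = d)
    reports <- reports[!duplicated(key3), , drop = FALSE]
  }

  reports <- reports[order(reports$person_id, reports$disease,
                           reports$report_wave), , drop = FALSE]
  out <- lapply(split(reports,
                      paste(reports$person_id, reports$disease, sep = "\r")),
                function(g) {
    onset <- NA_real_; wave <- NA_integer_; n_affirm <- 0L
    for (i in seq_len(nrow(g))) {
      age <- g$onset_age[i]
      if (isTRUE(g$accurate[i])) {
        n_affirm <- n_affirm + 1L
        if (!is.na(age)) { onset <- age; wave <- g$report_wave[i] }
      } else {
        if (!is.na(age)) {            # correction
          onset <- age; wave <- g$report_wave[i]; n_affirm <- n_affirm + 1L
        } else {                      # retraction without replacement
          onset <- NA_real_; wave <- NA_integer_; n_affirm <- 0L
        }
      }
    }
    if (is.na(onset)) return(NULL)
    data.frame(person_id = g$person_id[1], disease = g$disease[1],
               onset_age = onset, report_wave = wave,
               confirmed = n_affirm > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(person_id = character(), disease = character(),
                      onset_age = numeric(), report_wave = integer(),
                      confirmed = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' First chronic disease per participant
#'
#' Returns, for every participant with at least one onset event, the
#' disease(s) with the minimum onset age.  Ties (two or more diseases first
#' diagnosed in the same year) are all retained as co-first records and
#' flagged `tied = TRUE`; downstream direction counting treats such
#' same-year onsets as simultaneous.
#'
#' @param cohort A `traj_cohort`.
#' @return Data frame with columns `person_id`, `disease`, `onset_age`,
#'   `tied`.
#' @export
first_onsets <- function(cohort) {
  stopifnot(inherits(cohort, "traj_cohort"))
  ev <- cohort$events
  if (nrow(ev) == 0L)
    return(data.frame(person_id = character(), disease = character(),
                      onset_age = numeric(), tied = logical(),
                      stringsAsFactors = FALSE))
  min_age <- tapply(ev$onset_age, ev$person_id, min)
  keep <- ev$onset_age == min_age[ev$person_id]
  out <- ev[keep, c("person_id", "disease", "onset_age"), drop = FALSE]
  n_first <- table(out$person_id)
  out$tied <- as.vector(n_first[out$person_id] > 1L)
  out <- out[order(out$person_id, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multimorbidity category distribution
#'
#' Percentage of participants carrying 0, 1, 2, 3 or 4+ of the tracked
#' chronic diseases, optionally weighted by the individual survey weight.
#' Multimorbidity is conventionally the `2`, `3` and `4+` categories
#' combined (two or more co-occurring diseases).
#'
#' @param cohort A `traj_cohort`.
#' @param weighted Use participant survey weights (default `TRUE`).
#' @return Named numeric vector over categories `"0","1","2","3","4+"`,
#'   summing to 100.
#' @export
multimorbidity_distribution <- function(cohort, weighted = TRUE) {
  stopifnot(inherits(cohort, "traj_cohort"))
  p <- cohort$participants
  if (nrow(p) == 0L)
    traj_error("trajnet_validation_error",
               "cannot compute a distribution over an empty cohort")
  n_dis <- table(factor(cohort$events$person_id, levels = p$person_id))
  cat5 <- cut(as.vector(n_dis), breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("0", "1", "2", "3", "4+"))
  w <- if (weighted) p$weight else rep(1, nrow(p))
  mass <- tapply(w, cat5, sum, default = 0)
  out <- 100 * mass / sum(w)
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), names(mass))
}
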