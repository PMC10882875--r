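test_that("write_cohort / read_cohort round-trips a valid cohort", {
  parts <- mk_participants(c("a", "b", "c"))
  ev <- mk_events(c("a", "a", "b", "c"),
                  c("arthritis", "hypertension", "diabetes", "stroke"),
                  c(50, 55, 52, 56))
  co <- mk_cohort(parts, ev)
  ef <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, ef, pf)
  back <- read_cohort(ef, pf)
  expect_equal(back$participants, co$participants)
  expect_equal(back$events, co$events)
  expect_equal(nrow(back$participants), 3L)
  expect_equal(nrow(back$events), 4L)
})

test_that("malformed input raises classed errors naming the offender", {
  parts <- mk_participants(c("a", "b"))
  expect_error(
    mk_cohort(parts, mk_events("zz", "arthritis", 50)),
    class = "trajnet_integrity_error")
  err <- tryCatch(mk_cohort(parts, mk_events("zz", "arthritis", 50)),
                  condition = identity)
  expect_match(conditionMessage(err), "zz")

  expect_error(mk_cohort(parts, mk_events("a", "arthritis", -1)),
               class = "trajnet_validation_error")
  expect_error(mk_cohort(rbind(parts, parts)),
               class = "trajnet_integrity_error")
  expect_error(new_cohort(parts[, -2], NULL),
               class = "trajnet_schema_error")
  # onset after exit and duplicated (person, disease) are also rejected
  expect_error(mk_cohort(parts, mk_events("a", "arthritis", 99)),
               class = "trajnet_validation_error")
  expect_error(
    mk_cohort(parts, mk_events(c("a", "a"), "arthritis", c(50, 51))),
    class = "trajnet_integrity_error")
})

test_that("apply_exclusions counts per rule in order and partitions", {
  parts <- mk_participants(sprintf("p%d", 1:10))
  parts$exit_age[1:2] <- parts$entry_age[1:2]     # no follow-up
  parts$sex[3] <- NA                              # missing demographics
  co <- mk_cohort(parts, mk_events("p4", "arthritis", 52))
  res <- apply_exclusions(co)
  expect_equal(res$log$no_followup, 2L)
  expect_equal(res$log$missing_demog, 1L)
  expect_equal(res$log$retained, 7L)
  expect_equal(res$log$input, 10L)

  # a participant failing both rules is attributed to the first rule
  parts2 <- parts
  parts2$sex[1] <- NA
  res2 <- apply_exclusions(mk_cohort(parts2))
  expect_equal(res2$log$no_followup, 2L)
  expect_equal(res2$log$missing_demog, 1L)

  # no exclusions triggered: identity, all-zero log
  clean <- apply_exclusions(mk_cohort(mk_participants(c("x", "y"))))
  expect_equal(clean$log$no_followup, 0L)
  expect_equal(clean$log$missing_demog, 0L)
  expect_equal(clean$log$retained, 2L)
})

test_that("exclusion counts partition the input on random cohorts", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    parts <- mk_participants(sprintf("p%d", seq_len(n)))
    nofup <- runif(n) < 0.3
    parts$exit_age[nofup] <- parts$entry_age[nofup]
    parts$education[runif(n) < 0.2] <- NA
    log <- apply_exclusions(suppressWarnings(mk_cohort(parts)))$log
    expect_equal(log$no_followup + log$missing_demog + log$retained,
                 log$input)
  }
})

test_that("resolve_recall applies the latest-confirmed-report rule", {
  # confirmation keeps the original onset
  rep1 <- data.frame(person_id = "a", disease = "arthritis",
                     report_wave = c(2011, 2013), onset_age = c(50, NA),
                     accurate = TRUE, stringsAsFactors = FALSE)
  out1 <- resolve_recall(rep1)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$onset_age, 50)
  expect_true(out1$confirmed)

  # later wave marks the report inaccurate and corrects the age
  rep2 <- rep1; rep2$accurate <- c(TRUE, FALSE); rep2$onset_age <- c(50, 52)
  out2 <- resolve_recall(rep2)
  expect_equal(out2$onset_age, 52)
  expect_equal(out2$report_wave, 2013)

  # retraction without replacement deletes the event
  rep3 <- rep1; rep3$accurate <- c(TRUE, FALSE); rep3$onset_age <- c(50, NA)
  expect_equal(nrow(resolve_recall(rep3)), 0L)

  # conflicting duplicates within one wave are an integrity error
  rep4 <- data.frame(person_id = "a", disease = "arthritis",
                     report_wave = 2011, onset_age = c(50, 51),
                     accurate = TRUE, stringsAsFactors = FALSE)
  expect_error(resolve_recall(rep4), class = "trajnet_integrity_error")
})

test_that("first_onsets returns the argmin disease, ties flagged", {
  parts <- mk_participants(c("a", "b", "c"), entry_age = 40,
                           exit_age = 70)
  ev <- mk_events(c("a", "a", "c", "c"),
                  c("arthritis", "hypertension", "liver", "asthma"),
                  c(40, 50, 45, 45))
  fo <- first_onsets(mk_cohort(parts, ev, min_entry_age = 40))
  a <- fo[fo$person_id == "a", ]
  expect_equal(a$disease, "arthritis")
  expect_equal(a$onset_age, 40)
  expect_false(a$tied)
  expect_false("b" %in% fo$person_id)            # no events, no record
  cc <- fo[fo$person_id == "c", ]
  expect_setequal(cc$disease, c("liver", "asthma"))
  expect_true(all(cc$tied))
})

test_that("first onset age equals the brute-force per-person minimum", {
  co <- simulate_cohort(quick_sim(n = 500, hr = 2, seed = 9))$cohort
  fo <- first_onsets(co)
  mins <- tapply(co$events$onset_age, co$events$person_id, min)
  expect_equal(as.vector(mins[fo$person_id]), fo$onset_age)
})

test_that("multimorbidity distribution counts, sums and rescales", {
  parts <- mk_participants(c("a", "b", "c", "d"))
  dis <- c("hypertension", "dyslipidemia", "diabetes", "arthritis",
           "asthma")
  ev <- rbind(mk_events("b", dis[1], 50),
              mk_events(rep("c", 2), dis[1:2], 50),
              mk_events(rep("d", 5), dis, 50))
  co <- mk_cohort(parts, ev)
  mm <- multimorbidity_distribution(co, weighted = FALSE)
  expect_equal(unname(mm), c(25, 25, 25, 0, 25))
  expect_equal(sum(mm), 100, tolerance = 1e-9)

  # uniform weight rescaling leaves the distribution unchanged
  co2 <- co; co2$participants$weight <- co$participants$weight * 2
  expect_equal(multimorbidity_distribution(co2),
               multimorbidity_distribution(co))
})
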