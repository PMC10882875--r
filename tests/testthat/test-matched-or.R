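test_that("build_case_control enforces the risk-set and matching rules", {
  # one case with d2 at 60; five same-sex same-entry-age candidates, of
  # which two are ineligible (d2 before index; exited before index)
  parts <- mk_participants(sprintf("p%d", 1:8), entry_age = 50,
                           exit_age = 65)
  parts$exit_age[4] <- 58                 # out of observation at index 60
  parts$sex[5] <- "female"                # sex mismatch
  parts$entry_age[6] <- 56                # outside the +-2 caliper
  ev <- rbind(mk_events("p1", "hypertension", 60),
              mk_events("p1", "arthritis", 52),
              mk_events("p3", "hypertension", 58),  # d2 before index
              mk_events("p7", "arthritis", 55),     # exposed control
              mk_events("p8", "arthritis", 63))     # unexposed at index
  co <- mk_cohort(parts, ev)
  cfg <- match_config(ratio = 3, seed = 5)
  sets <- build_case_control(co, "arthritis", "hypertension", cfg)
  # p3 (incident d2 at 58) forms its own set; examine p1's set
  s1 <- sets[sets$set_id %in%
               sets$set_id[sets$person_id == "p1" &
                             sets$role == "case"], ]
  expect_equal(sum(s1$role == "control"), 3L)
  expect_false(any(c("p3", "p4", "p5", "p6") %in% s1$person_id))
  expect_true(s1$exposure[s1$person_id == "p1"])
  expect_true(s1$exposure[s1$person_id == "p7"])
  expect_false(s1$exposure[s1$person_id == "p8"])

  # more eligible controls than the ratio: exactly `ratio` sampled, seeded
  sets2 <- build_case_control(co, "arthritis", "hypertension", cfg)
  expect_identical(sets, sets2)
})

test_that("cases are exposure-enriched when a dependency is planted", {
  co <- simulate_cohort(quick_sim(n = 6000, hr = 3, seed = 13))$cohort
  sets <- build_case_control(co, "arthritis", "hypertension",
                             match_config(seed = 2))
  p_case <- mean(sets$exposure[sets$role == "case"])
  p_ctrl <- mean(sets$exposure[sets$role == "control"])
  expect_gt(p_case, p_ctrl)
})

test_that("clogit matches the 1:1 discordant-ratio closed form", {
  sets <- mk_sets(c(replicate(6, c(TRUE, FALSE), simplify = FALSE),
                    replicate(3, c(FALSE, TRUE), simplify = FALSE)))
  fit <- clogit_fit(sets)
  expect_equal(fit$or, 2, tolerance = 1e-6)
  expect_equal(fit$n_discordant, 9)
  expect_true(fit$converged)
})

test_that("clogit flags unidentifiable and separated designs", {
  concordant <- mk_sets(list(c(TRUE, TRUE), c(FALSE, FALSE, FALSE)))
  expect_error(clogit_fit(concordant),
               class = "trajnet_estimation_error")
  onesided <- mk_sets(replicate(5, c(TRUE, FALSE, FALSE),
                                simplify = FALSE))
  fit <- clogit_fit(onesided)
  expect_true(fit$separation)
  expect_true(is.infinite(fit$beta))
})

test_that("flipping every exposure negates beta exactly", {
  set.seed(17)
  for (i in 1:10) {
    pats <- replicate(30, sample(c(TRUE, FALSE), 4, replace = TRUE),
                      simplify = FALSE)
    sets <- mk_sets(pats)
    skip_ok <- tryCatch({f1 <- clogit_fit(sets); TRUE},
                        trajnet_estimation_error = function(e) FALSE)
    if (!skip_ok) next
    flipped <- sets; flipped$exposure <- !flipped$exposure
    f2 <- clogit_fit(flipped)
    if (f1$converged && f2$converged)
      expect_equal(f1$beta, -f2$beta, tolerance = 1e-6)
  }
})

test_that("clogit matches grid-search likelihood maximization on 1:3 sets", {
  set.seed(23)
  tested <- 0L
  while (tested < 25L) {
    pats <- replicate(sample(8:20, 1),
                      stats::runif(4) < stats::runif(1, 0.2, 0.8),
                      simplify = FALSE)
    sets <- mk_sets(pats)
    f <- tryCatch(clogit_fit(sets),
                  trajnet_estimation_error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    if (abs(f$beta) > 4.5) next           # keep inside the oracle grid
    expect_equal(f$beta, grid_clogit(sets), tolerance = 1e-4)
    tested <- tested + 1L
  }
})

test_that("bootstrap is deterministic, degenerate-safe, and tightens with n", {
  sets <- mk_sets(c(replicate(12, c(TRUE, FALSE, FALSE, FALSE),
                              simplify = FALSE),
                    replicate(6, c(FALSE, TRUE, FALSE, FALSE),
                              simplify = FALSE)))
  cfg <- match_config(bootstrap_reps = 100, seed = 9)
  ci1 <- bootstrap_ci(sets, cfg)
  ci2 <- bootstrap_ci(sets, cfg)
  expect_identical(ci1[c("ci_low", "ci_high")],
                   ci2[c("ci_low", "ci_high")])

  # a design with a single repeated discordant pattern is separated (the
  # score has one sign for any single pattern), so the point fit flags it
  # and the bootstrap reports total failure rather than a fake interval
  same <- mk_sets(replicate(8, c(TRUE, FALSE, TRUE, FALSE),
                            simplify = FALSE))
  expect_true(clogit_fit(same)$separation)
  expect_error(bootstrap_ci(same, cfg),
               class = "trajnet_estimation_error")

  # width shrinks when the same pattern mix is replicated fourfold
  wide <- mk_sets(c(replicate(10, c(TRUE, FALSE), simplify = FALSE),
                    replicate(5, c(FALSE, TRUE), simplify = FALSE)))
  narrow <- mk_sets(c(replicate(40, c(TRUE, FALSE), simplify = FALSE),
                      replicate(20, c(FALSE, TRUE), simplify = FALSE)))
  w1 <- with(bootstrap_ci(wide, cfg), log(ci_high) - log(ci_low))
  w2 <- with(bootstrap_ci(narrow, cfg), log(ci_high) - log(ci_low))
  expect_lt(w2, w1)
})

test_that("estimate_all_pairs applies the CI selection rule per pair", {
  co <- simulate_cohort(quick_sim(n = 8000, hr = 3, seed = 29))$cohort
  directed <- data.frame(source = "arthritis", target = "hypertension")
  est <- estimate_all_pairs(co, directed,
                            match_config(bootstrap_reps = 100, seed = 3,
                                         age_caliper = 0))
  expect_equal(nrow(est), 1L)
  expect_gt(est$or, 1)
  expect_true(est$selected == (est$or > 1 && est$ci_low > 1))
  expect_true(est$ci_low <= est$or && est$or <= est$ci_high)

  # per-pair seeds make results independent of execution order
  directed2 <- data.frame(source = c("zzz", "arthritis"),
                          target = c("hypertension", "hypertension"))
  est2 <- suppressWarnings(
    estimate_all_pairs(co, directed2,
                       match_config(bootstrap_reps = 100, seed = 3,
                                    age_caliper = 0)))
  expect_equal(est2$or[est2$source == "arthritis"], est$or)
})
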