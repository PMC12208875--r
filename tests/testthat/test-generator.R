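test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(resistant_fraction = 1.2), "resistant_fraction")
  expect_error(cohort_config(event_window_days = c(274, 183)), "event_window_days")
  expect_error(cohort_config(event_window_days = c(183, 400), followup_days = 365),
               "event_window_days")
  gm <- default_group_moments()
  gm$RDW$res[2] <- -1
  expect_error(cohort_config(group_moments = gm), "group_moments")
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  a <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
  b <- generate_cohort(cohort_config(n_patients = 100, seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_patients = 100, seed = 8))
  expect_false(identical(a$patients, c$patients))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_config(n_patients = 20, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("resistance probability reduces to the baseline when labs carry no information", {
  cfg <- cohort_config(discrimination_scale = 0, interaction_effect = 0,
                       baseline_logit = qlogis(733 / 1304))
  rec <- generate_cohort(cohort_config(n_patients = 5, seed = 3))$patients
  p <- resistance_probability(rec, cfg)
  expect_equal(p, rep(733 / 1304, 5), tolerance = 1e-12)
})

test_that("interaction term acts only inside the high-RDW/low-HGB quadrant", {
  rec <- generate_cohort(cohort_config(n_patients = 40, seed = 4))$patients
  q1 <- rec$RDW >= 17 & rec$HGB < 15.5
  expect_true(any(q1) && !all(q1))  # fixture exercises both sides
  p0 <- resistance_probability(rec, cohort_config(interaction_effect = 0))
  p5 <- resistance_probability(rec, cohort_config(interaction_effect = 5))
  p50 <- resistance_probability(rec, cohort_config(interaction_effect = 50))
  # outside the quadrant: untouched
  expect_equal(p5[!q1], p0[!q1], tolerance = 1e-12)
  # inside: monotone in the interaction strength, saturating at 1
  expect_true(all(p5[q1] > p0[q1]))
  expect_true(all(p50[q1] > 1 - 1e-9))
})

test_that("a missing required field raises an explicit error", {
  rec <- generate_cohort(cohort_config(n_patients = 3, seed = 1))$patients
  rec$WBC <- NULL
  expect_error(resistance_probability(rec, cohort_config()), "WBC")
})

test_that("resistant-group RDW matches the published moments at study scale", {
  coh <- generate_cohort(cohort_config(n_patients = 1304, seed = 1))
  res <- coh$outcome$resistant
  se <- 3.22 / sqrt(sum(res))
  expect_lt(abs(mean(coh$patients$RDW[res]) - 18.1), 3 * se)
})

test_that("group-conditional moments are recovered for every lab variable", {
  # with no planted interaction the configured moments are the exact
  # group-conditional generative moments
  coh <- generate_cohort(cohort_config(n_patients = 6000, seed = 2,
                                       interaction_effect = 0))
  res <- coh$outcome$resistant
  gm <- default_group_moments()
  for (v in c("RDW", "HGB", "HCT", "WBC", "ANC", "RBC", "PLT", "lymphocytes",
              "age_at_index")) {
    for (g in c(TRUE, FALSE)) {
      tgt <- if (g) gm[[v]]$res else gm[[v]]$non
      x <- coh$patients[[v]][res == g]
      se_mean <- tgt[2] / sqrt(length(x))
      se_sd <- tgt[2] / sqrt(2 * length(x))
      expect_lt(abs(mean(x) - tgt[1]), 3 * se_mean)
      expect_lt(abs(sd(x) - tgt[2]), 3 * se_sd)
    }
  }
})

test_that("a strong planted interaction enriches the high-RDW/low-HGB quadrant", {
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 400, seed = 100 + s,
                                         interaction_effect = 2.5))
    p <- coh$patients
    q1 <- p$RDW >= 17 & p$HGB < 15.5
    res <- coh$outcome$resistant
    mean(res[q1]) > mean(res)
  }, logical(1))
  expect_true(all(hits))
})

test_that("ground-truth outcome matches the planted timeline manifestation", {
  coh <- generate_cohort(cohort_config(n_patients = 300, seed = 9))
  out <- coh$outcome
  expect_identical(out$criterion == "none", !out$resistant)
  expect_true(all(out$event_day[out$resistant] >= 183 &
                  out$event_day[out$resistant] < 274))
  expect_true(all(out$event_day[!out$resistant] == 365))
})
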