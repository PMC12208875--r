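test_that("an all-eligible cohort passes every funnel stage", {
  coh <- generate_cohort(cohort_config(n_patients = 30, seed = 6))
  f <- apply_inclusion_funnel(coh$patients, coh$events)
  expect_true(all(f$report$remaining == 30))
  expect_equal(nrow(f$patients), 30)
})

test_that("funnel excludes under-age patients and single-prescription patients", {
  pats <- rbind(eligible_patient("A", age = 17), eligible_patient("B"),
                eligible_patient("C"))
  evs <- rbind(eligible_timeline("A"), eligible_timeline("B"),
               eligible_timeline("C"))
  # patient B loses one HU prescription
  evs <- evs[!(evs$patient_id == "B" & evs$kind == "hu_prescription" &
               evs$day_offset == 90), ]
  f <- apply_inclusion_funnel(pats, evs)
  expect_equal(f$patients$patient_id, "C")
  rep <- f$report
  # A drops exactly at the age stage, B exactly at the prescription stage
  expect_equal(rep$remaining[rep$stage == "hu_index"], 3)
  expect_equal(rep$remaining[rep$stage == "age"], 2)
  expect_equal(rep$remaining[rep$stage == "pv_before_hu"], 2)
  expect_equal(rep$remaining[rep$stage == "min_hu_prescriptions"], 1)
})

test_that("funnel excludes MF/ET diagnoses and competing cytoreductives", {
  pats <- rbind(eligible_patient("A"), eligible_patient("B"), eligible_patient("C"))
  ext <- function(pid, day, kind)
    data.frame(patient_id = pid, day_offset = day, kind = kind,
               analyte = NA, value = NA, stringsAsFactors = FALSE)
  evs <- rbind(eligible_timeline("A", ext("A", 50L, "mf_diagnosis")),
               eligible_timeline("B", ext("B", 100L, "rux_prescription")),
               eligible_timeline("C", ext("C", 300L, "rux_prescription")))
  f <- apply_inclusion_funnel(pats, evs)
  # C's ruxolitinib falls beyond the HU-only span and is tolerated
  expect_equal(f$patients$patient_id, "C")
})

test_that("funnel counts never increase and missing timelines are reported", {
  coh <- generate_cohort(cohort_config(n_patients = 50, seed = 10))
  coh$patients$age_at_index[1:5] <- 15
  f <- apply_inclusion_funnel(coh$patients, coh$events)
  expect_true(all(diff(f$report$remaining) <= 0))
  expect_equal(f$report$remaining[nrow(f$report)], 45)
  orphan <- coh$events$patient_id != "P00001"
  expect_error(apply_inclusion_funnel(coh$patients, coh$events[orphan, ]),
               "P00001")
})

test_that("resistance labeling applies the window rules in priority order", {
  tl <- function(extra) {
    df <- rbind(data.frame(patient_id = "X", day_offset = c(-20L, 0L),
                           kind = c("lab", "hu_prescription"),
                           analyte = c("HCT", NA), value = c(44, NA),
                           stringsAsFactors = FALSE), extra)
    df[order(df$day_offset), ]
  }
  ev <- function(day, kind, analyte = NA, value = NA)
    data.frame(patient_id = "X", day_offset = as.integer(day), kind = kind,
               analyte = analyte, value = value, stringsAsFactors = FALSE)

  # (a) phlebotomy inside the window
  l <- label_hu_res(tl(ev(200, "phlebotomy")))
  expect_true(l$resistant)
  expect_equal(l$criterion, "phlebotomy_in_window")
  expect_equal(l$event_day, 200L)

  # (b) uncontrolled hematocrit
  l <- label_hu_res(tl(ev(250, "lab", "HCT", 46)))
  expect_equal(l$criterion, "hct_uncontrolled")
  expect_equal(l$event_day, 250L)

  # (c) leukocytosis + thrombocytosis within the pairing tolerance
  l <- label_hu_res(tl(rbind(ev(220, "lab", "WBC", 12), ev(230, "lab", "PLT", 450))))
  expect_equal(l$criterion, "myeloproliferation_uncontrolled")
  expect_equal(l$event_day, 220L)
  # pairing beyond the tolerance does not trigger
  l <- label_hu_res(tl(rbind(ev(190, "lab", "WBC", 12), ev(240, "lab", "PLT", 450))))
  expect_false(l$resistant)

  # priority: phlebotomy beats a later-but-higher-priority-date HCT trigger
  l <- label_hu_res(tl(rbind(ev(250, "phlebotomy"), ev(200, "lab", "HCT", 48))))
  expect_equal(l$criterion, "phlebotomy_in_window")

  # nothing qualifying: censored at follow-up end
  l <- label_hu_res(tl(ev(250, "lab", "HCT", 42)))
  expect_false(l$resistant)
  expect_equal(l$criterion, "none")
  expect_equal(l$event_day, 365L)

  # tolerance extends the window on both sides
  expect_true(label_hu_res(tl(ev(170, "phlebotomy")))$resistant)
  expect_true(label_hu_res(tl(ev(287, "phlebotomy")))$resistant)
  expect_false(label_hu_res(tl(ev(168, "phlebotomy")))$resistant)
  expect_false(label_hu_res(tl(ev(288, "phlebotomy")))$resistant)

  # contract violations
  bad <- tl(ev(200, "phlebotomy"))
  expect_error(label_hu_res(bad[rev(seq_len(nrow(bad))), ]), "sorted")
  expect_error(label_hu_res(bad, window = c(183L, 400L)), "follow-up")
})

test_that("labeling recovers the generator's ground truth", {
  coh <- generate_cohort(cohort_config(n_patients = 800, seed = 11))
  lab <- label_cohort(coh$events)
  expect_gte(mean(lab$resistant == coh$outcome$resistant), 0.99)
  expect_gte(mean(lab$criterion == coh$outcome$criterion), 0.99)
})

test_that("feature derivation follows the stated definitions", {
  pat <- data.frame(patient_id = "X", gender = "female", age_at_index = 60,
                    te_history = FALSE, weight = 80, stringsAsFactors = FALSE)
  ev <- function(day, kind, analyte = NA, value = NA)
    data.frame(patient_id = "X", day_offset = as.integer(day), kind = kind,
               analyte = analyte, value = value, stringsAsFactors = FALSE)
  tl <- rbind(ev(-400, "pv_diagnosis"),
              ev(-150, "phlebotomy"), ev(-10, "phlebotomy"),
              ev(-40, "lab", "ANC", 6.0), ev(-40, "lab", "lymphocytes", 1.0),
              ev(-90, "lab", "RDW", 18.2), ev(-30, "lab", "RDW", 17.5),
              ev(10, "lab", "RDW", 99))   # post-index: must be ignored
  tl <- tl[order(tl$day_offset), ]

  f <- derive_features(pat, tl, pre_index_days = 183L)
  expect_equal(f$NLR, 6.0)
  expect_equal(f$annualized_phlebotomy_count, 2 * 365 / 183)
  expect_equal(f$time_dx_to_tx, 400)
  expect_equal(f$RDW, 17.5)   # most recent pre-index value
  expect_true(is.na(f$HGB))   # never measured

  # missing lymphocytes: NLR missing, everything else intact
  tl2 <- tl[!(tl$kind == "lab" & tl$analyte == "lymphocytes"), ]
  f2 <- derive_features(pat, tl2, pre_index_days = 183L)
  expect_true(is.na(f2$NLR))
  expect_equal(f2$ANC, 6.0)
  expect_equal(f2$RDW, 17.5)
})

test_that("derived features reproduce the generator's baseline records", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 12))
  feat <- derive_feature_table(coh$patients, coh$events)
  for (v in c("RDW", "HGB", "HCT", "WBC", "ANC", "NLR",
              "annualized_phlebotomy_count"))
    expect_equal(feat[[v]], coh$patients[[v]])
  expect_equal(feat$time_dx_to_tx, as.numeric(coh$patients$time_dx_to_tx))
})
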