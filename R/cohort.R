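#' Inclusion criteria for the analysis cohort
#'
#' Parameters of the inclusion/exclusion funnel applied by
#' [apply_inclusion_funnel()]: adults with a polycythemia vera diagnosis
#' preceding their first hydroxyurea (HU) prescription, at least two HU
#' prescriptions, no myelofibrosis or essential thrombocythemia diagnosis, no
#' other cytoreductive therapy (ruxolitinib, interferon, busulfan, ...)
#' during the HU-only span, a documented pre-index history of at least six
#' months and twelve months of post-index follow-up.
#'
#' @param min_age minimum age (years) at the index date; default 18.
#' @param pre_index_history_days required documented history before the index
#'   date; default 183 (6 months at 30.44 days/month).
#' @param post_index_followup_days required follow-up after the index date;
#'   default 365.
#' @param min_hu_prescriptions minimum number of HU prescription events;
#'   default 2.
#' @param hu_only_days span (days after index) during which ruxolitinib or
#'   other cytoreductive events lead to exclusion; default 274 (9 months).
#' @param require_lab_in_pre_index if `TRUE` (default), at least one
#'   laboratory result must fall in the pre-index history window.
#' @return an object of class `inclusion_criteria`.
#' @export
inclusion_criteria <- function(min_age = 18,
                               pre_index_history_days = 183L,
                               post_index_followup_days = 365L,
                               min_hu_prescriptions = 2L,
                               hu_only_days = 274L,
                               require_lab_in_pre_index = TRUE) {
  cr <- list(min_age = min_age,
             pre_index_history_days = as.integer(pre_index_history_days),
             post_index_followup_days = as.integer(post_index_followup_days),
             min_hu_prescriptions = as.integer(min_hu_prescriptions),
             hu_only_days = as.integer(hu_only_days),
             require_lab_in_pre_index = isTRUE(require_lab_in_pre_index))
  if (cr$pre_index_history_days <= 0L || cr$post_index_followup_days <= 0L ||
      cr$hu_only_days <= 0L)
    stop("all inclusion criteria durations must be positive", call. = FALSE)
  if (cr$min_hu_prescriptions < 1L)
    stop("min_hu_prescriptions must be at least 1", call. = FALSE)
  class(cr) <- "inclusion_criteria"
  cr
}

#' Apply the inclusion/exclusion funnel
#'
#' Filters a cohort stage by stage and reports the attrition. Stage order is
#' fixed: `all`, `hu_index` (an HU prescription anchors day 0),
#' `age` (>= `min_age` at index), `pv_before_hu` (first HU after the initial
#' PV diagnosis), `min_hu_prescriptions`, `no_mf_et`, `hu_only` (no
#' ruxolitinib / other cytoreductive before day `hu_only_days`), `history`,
#' `followup`, and optionally `pre_index_lab`.
#'
#' @param patients patient table (one row per patient, `patient_id` column).
#' @param events event table in the [read_cohort()] schema; every patient in
#'   `patients` must have at least one event row.
#' @param criteria an [inclusion_criteria()] object.
#' @return list with `patients` and `events` restricted to the retained
#'   cohort, and `report`, a `funnel_report` data.frame of
#'   `(stage, remaining)` with non-increasing counts.
#' @export
apply_inclusion_funnel <- function(patients, events, criteria = inclusion_criteria()) {
  stopifnot(inherits(criteria, "inclusion_criteria"))
  validate_events(events)
  no_tl <- setdiff(patients$patient_id, unique(events$patient_id))
  if (length(no_tl))
    stop("patients without a timeline: ", paste(no_tl, collapse = ", "),
         call. = FALSE)

  ev <- events[events$patient_id %in% patients$patient_id, ]
  byp <- split(ev, factor(ev$patient_id, levels = patients$patient_id))

  summ <- function(f) vapply(byp, f, logical(1))
  keep <- rep(TRUE, nrow(patients))
  report <- data.frame(stage = "all", remaining = nrow(patients),
                       stringsAsFactors = FALSE)
  push <- function(stage, ok) {
    keep <<- keep & ok
    report <<- rbind(report, data.frame(stage = stage, remaining = sum(keep),
                                        stringsAsFactors = FALSE))
  }

  push("hu_index", summ(function(d) any(d$kind == "hu_prescription")))
  push("age", !is.na(patients$age_at_index) & patients$age_at_index >= criteria$min_age)
  push("pv_before_hu",
       summ(function(d) any(d$kind == "pv_diagnosis" & d$day_offset < 0L)))
  push("min_hu_prescriptions",
       summ(function(d) sum(d$kind == "hu_prescription") >= criteria$min_hu_prescriptions))
  push("no_mf_et",
       summ(function(d) !any(d$kind %in% c("mf_diagnosis", "et_diagnosis"))))
  push("hu_only",
       summ(function(d) !any(d$kind %in% c("rux_prescription", "other_cytoreductive") &
                             d$day_offset < criteria$hu_only_days)))
  push("history",
       summ(function(d) min(d$day_offset) <= -criteria$pre_index_history_days))
  push("followup",
       summ(function(d) max(d$day_offset) >= criteria$post_index_followup_days))
  if (criteria$require_lab_in_pre_index)
    push("pre_index_lab",
         summ(function(d) any(d$kind == "lab" &
                              d$day_offset >= -criteria$pre_index_history_days &
                              d$day_offset < 0L)))

  class(report) <- c("funnel_report", "data.frame")
  ids <- patients$patient_id[keep]
  list(patients = patients[keep, , drop = FALSE],
       events = ev[ev$patient_id %in% ids, , drop = FALSE],
       report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Inclusion funnel:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-22s %6d\n", x$stage[i], x$remaining[i]))
  invisible(x)
}

#' Label hydroxyurea resistance in the post-index window
#'
#' Applies the real-world-evidence adaptation of the ELN consensus criteria
#' (the hydroxyurea dose clause is dropped, as no dosing information exists
#' in EHR-style data). A patient is resistant if, inside
#' `[window[1] - tolerance, window[2] + tolerance)` days after the index,
#' any of the following holds, checked in this priority order:
#' (a) at least one phlebotomy; (b) any hematocrit measurement >= 45%;
#' (c) a WBC measurement > 10 x 10^9/L paired with a platelet measurement
#' > 400 x 10^9/L taken within `tolerance_days` of each other.
#'
#' @param timeline event data.frame of a single patient (schema of
#'   [read_cohort()]), sorted by `day_offset`.
#' @param window integer `c(start, end)`, half-open post-index window in
#'   days; default `c(183, 274)` (months 6-9).
#' @param tolerance_days measurement tolerance around the window (and for the
#'   WBC/platelet pairing); default 14.
#' @param followup_days end of follow-up; censoring day for non-resistant
#'   patients. The window must lie within follow-up.
#' @return list of class `hu_label`: `resistant` (logical), `criterion`
#'   (one of `"phlebotomy_in_window"`, `"hct_uncontrolled"`,
#'   `"myeloproliferation_uncontrolled"`, `"none"`), `event_day` (day of the
#'   triggering event, or `followup_days` if censored).
#' @export
label_hu_res <- function(timeline, window = c(183L, 274L), tolerance_days = 14L,
                         followup_days = 365L) {
  if (is.unsorted(timeline$day_offset))
    stop("timeline must be sorted by day_offset", call. = FALSE)
  if (window[1] >= window[2])
    stop("window must satisfy start < end", call. = FALSE)
  if (window[1] < 0L || window[2] > followup_days)
    stop("labeling window must lie within follow-up", call. = FALSE)
  lo <- window[1] - tolerance_days
  hi <- window[2] + tolerance_days
  inw <- timeline$day_offset >= lo & timeline$day_offset < hi

  res <- function(criterion, day)
    structure(list(resistant = TRUE, criterion = criterion,
                   event_day = as.integer(day)), class = "hu_label")

  ## (a) phlebotomy need despite hydroxyurea
  ph <- timeline$day_offset[inw & timeline$kind == "phlebotomy"]
  if (length(ph)) return(res("phlebotomy_in_window", min(ph)))

  ## (b) uncontrolled hematocrit
  lab <- timeline[inw & timeline$kind == "lab", , drop = FALSE]
  hct <- lab[!is.na(lab$analyte) & lab$analyte == "HCT" &
             !is.na(lab$value) & lab$value >= 45, , drop = FALSE]
  if (nrow(hct)) return(res("hct_uncontrolled", min(hct$day_offset)))

  ## (c) persistent myeloproliferation: leukocytosis + thrombocytosis
  wbc <- lab[!is.na(lab$analyte) & lab$analyte == "WBC" &
             !is.na(lab$value) & lab$value > 10, , drop = FALSE]
  plt <- lab[!is.na(lab$analyte) & lab$analyte == "PLT" &
             !is.na(lab$value) & lab$value > 400, , drop = FALSE]
  if (nrow(wbc) && nrow(plt)) {
    for (d in sort(wbc$day_offset)) {
      if (any(abs(plt$day_offset - d) <= tolerance_days))
        return(res("myeloproliferation_uncontrolled", d))
    }
  }

  structure(list(resistant = FALSE, criterion = "none",
                 event_day = as.integer(followup_days)), class = "hu_label")
}

#' Label every patient of a cohort
#'
#' Vectorized wrapper around [label_hu_res()].
#'
#' @param events event table for the whole cohort.
#' @param patient_ids patients to label (default: all ids present).
#' @inheritParams label_hu_res
#' @return data.frame: `patient_id`, `resistant`, `criterion`, `event_day`.
#' @export
label_cohort <- function(events, patient_ids = unique(events$patient_id),
                         window = c(183L, 274L), tolerance_days = 14L,
                         followup_days = 365L) {
  byp <- split(events, factor(events$patient_id, levels = patient_ids))
  lab <- lapply(byp, label_hu_res, window = window,
                tolerance_days = tolerance_days, followup_days = followup_days)
  data.frame(patient_id = patient_ids,
             resistant = vapply(lab, `[[`, logical(1), "resistant"),
             criterion = vapply(lab, `[[`, character(1), "criterion"),
             event_day = vapply(lab, `[[`, integer(1), "event_day"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive the pre-index feature vector for one patient
#'
#' Baseline laboratory features are the most recent pre-index value per
#' analyte; the neutrophil-to-lymphocyte ratio is ANC / lymphocytes (missing
#' when either is missing); the annualized phlebotomy count is the number of
#' pre-index phlebotomies scaled to events per year; `time_dx_to_tx` is the
#' number of days from the first PV diagnosis to the index date. Demographics
#' (`gender`, `age_at_index`, `te_history`, `weight`) are carried over from
#' the patient record. Missing data propagate as `NA`.
#'
#' @param patient one-row data.frame with at least `patient_id`; demographic
#'   columns are carried over when present.
#' @param timeline the patient's event data.frame.
#' @param pre_index_days length of the pre-index window in days (default 183).
#' @return one-row data.frame of features.
#' @export
derive_features <- function(patient, timeline, pre_index_days = 183L) {
  if (pre_index_days <= 0) stop("pre_index_days must be positive", call. = FALSE)
  analytes <- c("RBC", "HCT", "HGB", "RDW", "WBC", "ANC", "lymphocytes", "PLT")
  pre <- timeline[timeline$day_offset < 0L &
                  timeline$day_offset >= -pre_index_days, , drop = FALSE]
  out <- data.frame(patient_id = patient$patient_id, stringsAsFactors = FALSE)
  for (col in c("gender", "age_at_index", "te_history", "weight"))
    out[[col]] <- if (col %in% names(patient)) patient[[col]] else NA

  dx <- timeline$day_offset[timeline$kind == "pv_diagnosis"]
  out$time_dx_to_tx <- if (length(dx)) -min(dx) else NA_real_
  out$annualized_phlebotomy_count <-
    sum(pre$kind == "phlebotomy") * 365 / pre_index_days

  labs <- pre[pre$kind == "lab" & !is.na(pre$analyte), , drop = FALSE]
  for (a in analytes) {
    rows <- labs[labs$analyte == a, , drop = FALSE]
    out[[a]] <- if (nrow(rows)) rows$value[which.max(rows$day_offset)] else NA_real_
  }
  out$NLR <- out$ANC / out$lymphocytes
  out
}

#' Derive the feature table for a whole cohort
#'
#' @param patients patient table; @param events cohort event table.
#' @inheritParams derive_features
#' @return data.frame, one row per patient, in the order of `patients`.
#' @export
derive_feature_table <- function(patients, events, pre_index_days = 183L) {
  byp <- split(events, factor(events$patient_id, levels = patients$patient_id))
  rows <- lapply(seq_len(nrow(patients)), function(i)
    derive_features(patients[i, , drop = FALSE], byp[[i]], pre_index_days))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
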