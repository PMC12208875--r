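#' Read and write cohorts as CSV tables
#'
#' A cohort on disk is a directory holding `patients.csv` (one row per
#' patient; the column schema of the `patients` element of [generate_cohort()])
#' and `events.csv` (long format: `patient_id`, `day_offset`, `kind`,
#' `analyte`, `value`; sorted by patient and day offset, day 0 = index date).
#' If ground truth is available an `outcome.csv` is written alongside.
#' Files are UTF-8, RFC-4180 quoted CSV. `read_cohort()` validates the event
#' table (known event kinds, lab events carry analyte and value, timelines
#' sorted) and reports the offending row on failure.
#'
#' @param cohort a `pv_cohort` (or any list with `patients`/`events` and
#'   optionally `outcome` data.frames).
#' @param path directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a list of class `pv_cohort` with `patients`, `events` and, when present
#'   on disk, `outcome`.
#' @export
write_cohort <- function(cohort, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write.csv(cohort$patients, file.path(path, "patients.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(cohort$events, file.path(path, "events.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(cohort$outcome))
    write.csv(cohort$outcome, file.path(path, "outcome.csv"),
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

event_kinds <- function() {
  c("hu_prescription", "rux_prescription", "other_cytoreductive",
    "phlebotomy", "lab", "pv_diagnosis", "mf_diagnosis", "et_diagnosis",
    "te_event")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  pfile <- file.path(path, "patients.csv")
  efile <- file.path(path, "events.csv")
  for (f in c(pfile, efile))
    if (!file.exists(f)) stop("cohort file not found: ", f, call. = FALSE)
  patients <- read.csv(pfile, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  events <- read.csv(efile, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                     colClasses = c(patient_id = "character", day_offset = "integer",
                                    kind = "character", analyte = "character",
                                    value = "numeric"))
  validate_events(events)
  out <- list(patients = patients, events = events)
  ofile <- file.path(path, "outcome.csv")
  if (file.exists(ofile))
    out$outcome <- read.csv(ofile, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(out) <- "pv_cohort"
  out
}

validate_events <- function(events) {
  need <- c("patient_id", "day_offset", "kind", "analyte", "value")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(events) == 0L) return(invisible(events))
  bad <- which(!events$kind %in% event_kinds())
  if (length(bad))
    stop(sprintf("unknown event kind '%s' at events row %d",
                 events$kind[bad[1]], bad[1]), call. = FALSE)
  lab <- events$kind == "lab"
  bad <- which(lab & (is.na(events$analyte) | is.na(events$value)))
  if (length(bad))
    stop(sprintf("lab event missing analyte/value at events row %d", bad[1]),
         call. = FALSE)
  ## per-patient day offsets must be non-decreasing
  unsorted <- which(diff(events$day_offset) < 0 &
                    events$patient_id[-1] == events$patient_id[-nrow(events)])
  if (length(unsorted))
    stop(sprintf("timeline not sorted by day_offset at events row %d",
                 unsorted[1] + 1L), call. = FALSE)
  invisible(events)
}
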