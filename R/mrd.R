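# Longitudinal MRD tracking.
#
# A patient series is an ordered set of timepoints, each carrying a
# quantification result. Status transitions are called from the
# detectability sequence: molecular response (first negativity after
# positivity), sustained negativity, molecular recurrence (positivity after
# documented negativity) and rising/falling trends among detectable points.
# Detectability itself is delegated entirely to the quantification module;
# the tracking logic never re-thresholds concentrations.

.status_vocab <- c("baseline_positive", "molecular_response",
                   "sustained_negativity", "molecular_recurrence",
                   "rising", "falling", "invalid_qc", "none")

#' Build a timepoints data.frame row
#'
#' @param patient patient identifier.
#' @param date collection date (`Date` or parseable string).
#' @param quant a `quant_result` from [quantify_sample()].
#' @param days_since_diagnosis optional non-negative day offset.
#' @param annotation optional free-text clinical annotation.
#' @return one-row data.frame.
#' @export
time_point <- function(patient, date, quant, days_since_diagnosis = NA,
                       annotation = NA_character_) {
  stopifnot(inherits(quant, "quant_result"))
  date <- as.Date(date)
  if (is.na(date)) stopf("invalid collection date for patient %s", patient)
  if (!is.na(days_since_diagnosis) && days_since_diagnosis < 0)
    stopf("days_since_diagnosis must be >= 0")
  data.frame(
    patient = patient, date = date, assay = quant$assay,
    days_since_diagnosis = as.numeric(days_since_diagnosis),
    copies_per_mL = quant$copies_per_mL_plasma,
    allelic_fraction = quant$allelic_fraction,
    detectability = quant$detectability,
    qc_flags = paste(quant$qc_flags, collapse = ";"),
    valid = quant$valid,
    annotation = annotation,
    stringsAsFactors = FALSE
  )
}

#' Build a patient series from timepoints
#'
#' Sorts timepoints by date; duplicate (date, assay) combinations and mixed
#' patients are validation errors. QC-invalid points are retained but
#' excluded from status logic.
#'
#' @param timepoints data.frame of rows from [time_point()] (or an
#'   equivalent layout with columns `patient`, `date`, `assay`,
#'   `copies_per_mL`, `detectability`, `valid`).
#' @return object of class `patient_series`.
#' @export
build_series <- function(timepoints) {
  if (!is.data.frame(timepoints) || nrow(timepoints) == 0)
    stopf("timepoints must be a nonempty data.frame")
  req <- c("patient", "date", "assay", "copies_per_mL", "detectability",
           "valid")
  miss <- setdiff(req, names(timepoints))
  if (length(miss)) stopf("timepoints lack columns: %s",
                          paste(miss, collapse = ", "))
  pats <- unique(timepoints$patient)
  if (length(pats) != 1)
    stopf("timepoints mix patients: %s", paste(pats, collapse = ", "))
  timepoints$date <- as.Date(timepoints$date)
  tp <- timepoints[order(timepoints$date, timepoints$assay), , drop = FALSE]
  key <- paste(tp$date, tp$assay)
  if (anyDuplicated(key))
    stopf("duplicate (date, assay) timepoints: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(tp) <- NULL
  structure(list(patient = pats, timepoints = tp), class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> %s: %d timepoints (%s to %s)\n", x$patient,
              nrow(x$timepoints), min(x$timepoints$date),
              max(x$timepoints$date)))
  invisible(x)
}

#' Call MRD status per timepoint
#'
#' Works left-to-right over QC-valid timepoints, so appending a timepoint
#' never changes earlier calls. Rules: `baseline_positive` when the first
#' valid point is detectable; `molecular_response` at the first undetectable
#' point after a detectable one; `sustained_negativity` from the second
#' consecutive undetectable point; `molecular_recurrence` at a detectable
#' point following documented negativity; `rising`/`falling` from the third
#' point of a strictly increasing/decreasing run of copies/mL among
#' consecutive detectable points. Borderline points are inconclusive and
#' break both negativity and positivity runs. QC-invalid points are marked
#' `invalid_qc` and skipped.
#'
#' @param series a `patient_series`.
#' @return character vector of status calls, one per timepoint (in series
#'   order); points with no call are `"none"`.
#' @export
call_status <- function(series) {
  stopifnot(inherits(series, "patient_series"))
  tp <- series$timepoints
  status <- rep("none", nrow(tp))
  status[!tp$valid] <- "invalid_qc"
  idx <- which(tp$valid)
  if (!length(idx)) stopf("no evaluable series: all timepoints QC-invalid")
  prev_concl <- NA_character_   # last non-borderline detectability
  neg_run <- 0L                 # consecutive undetectable points
  run_dir <- 0L                 # +1 rising / -1 falling trend direction
  run_len <- 0L                 # length of current monotone detectable run
  last_cpm <- NA_real_
  first_valid <- TRUE
  for (i in idx) {
    d <- tp$detectability[i]
    if (d == "borderline") {
      neg_run <- 0L; run_len <- 0L; run_dir <- 0L; last_cpm <- NA_real_
    } else if (d == "undetectable") {
      neg_run <- neg_run + 1L
      if (identical(prev_concl, "detectable")) {
        status[i] <- "molecular_response"
      } else if (neg_run >= 2L) {
        status[i] <- "sustained_negativity"
      }
      prev_concl <- "undetectable"
      run_len <- 0L; run_dir <- 0L; last_cpm <- NA_real_
    } else { # detectable
      if (first_valid) {
        status[i] <- "baseline_positive"
      } else if (identical(prev_concl, "undetectable")) {
        status[i] <- "molecular_recurrence"
      }
      cpm <- tp$copies_per_mL[i]
      if (run_len >= 1L && !is.na(last_cpm)) {
        dir <- sign(cpm - last_cpm)
        if (dir != 0 && (run_dir == 0L || dir == run_dir)) {
          run_dir <- dir
          run_len <- run_len + 1L
        } else {
          run_dir <- 0L
          run_len <- 1L
        }
      } else {
        run_len <- 1L
      }
      if (run_len >= 3L && status[i] == "none")
        status[i] <- if (run_dir > 0) "rising" else "falling"
      last_cpm <- cpm
      neg_run <- 0L
      prev_concl <- "detectable"
    }
    first_valid <- FALSE
  }
  status
}

#' Export a patient series (with status calls) as CSV
#'
#' @param series a `patient_series`.
#' @param path output path.
#' @return the exported data.frame, invisibly.
#' @export
export_series <- function(series, path) {
  stopifnot(inherits(series, "patient_series"))
  tp <- series$timepoints
  tp$status <- call_status(series)
  data.table::fwrite(tp, path)
  invisible(tp)
}

#' Re-read a series CSV written by [export_series()]
#'
#' @param path CSV path.
#' @return a `patient_series` (the `status` column is dropped and can be
#'   recomputed with [call_status()]).
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stopf("series CSV not found: %s", path)
  df <- as.data.frame(data.table::fread(path))
  df$status <- NULL
  build_series(df)
}

#' Plot-ready arrays for a patient series
#'
#' Returns timepoint-aligned vectors; zeros are retained (log-scale handling
#' is the renderer's concern).
#'
#' @param series a `patient_series`.
#' @return list with `dates`, `copies_per_mL`, `statuses`.
#' @export
plot_data <- function(series) {
  stopifnot(inherits(series, "patient_series"))
  list(dates = series$timepoints$date,
       copies_per_mL = series$timepoints$copies_per_mL,
       statuses = call_status(series))
}
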