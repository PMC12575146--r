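#' A single patient-visit event
#'
#' One row of the longitudinal EHR: a dated visit carrying whichever of
#' the tabular features were recorded (department, procedure, therapy and
#' subtherapy, biological marker measurements, tumor size) plus an
#' optional free-text report. Everything but the date may be missing;
#' missing features are simply skipped at tokenization.
#'
#' @param date Visit date (Date or ISO-8601 string). Required.
#' @param department,procedure,therapy,subtherapy Categorical strings or
#'   `NA`.
#' @param bio_values Named numeric vector/list of marker measurements
#'   (names matching the marker panel), or `NULL`.
#' @param tumor_size_cm Non-negative tumor size in cm, or `NA`.
#' @param report_text Free-text report, or `NA`.
#' @return An object of class `visit_event`.
#' @export
visit_event <- function(date, department = NA, procedure = NA,
                        therapy = NA, subtherapy = NA, bio_values = NULL,
                        tumor_size_cm = NA, report_text = NA) {
  if (missing(date) || is.null(date) || is.na(date)) {
    stop_input("visit_event requires a date")
  }
  v <- structure(
    list(date = as_date(date), department = department,
         procedure = procedure, therapy = therapy, subtherapy = subtherapy,
         bio_values = bio_values, tumor_size_cm = tumor_size_cm,
         report_text = report_text),
    class = "visit_event"
  )
  has_content <- !is.na(department) || !is.na(procedure) ||
    !is.na(therapy) || !is.na(subtherapy) ||
    (!is.null(bio_values) && any(!is.na(unlist(bio_values)))) ||
    !is.na(tumor_size_cm) || !is.na(report_text)
  if (!has_content) {
    stop_input("visit_event needs at least one non-missing field besides date")
  }
  v
}

#' A patient record
#'
#' The unit the whole pipeline consumes: static clinical features, the
#' chronologically ordered visit history, and the outcome (disease-free
#' survival event indicator and follow-up measured from surgery).
#'
#' @param patient_id Identifier string.
#' @param birth_date,diagnosis_date,surgery_date Dates;
#'   `surgery_date >= diagnosis_date`.
#' @param visits List of [visit_event()]s; sorted by date on creation.
#' @param molecular_subtype One of `"Luminal"`, `"TNBC"`, `"HER2+/RH-"`,
#'   `"HER2+/RH+"`, or `NA`.
#' @param tumor_grade 1, 2, 3 or `NA`.
#' @param n_nodes Non-negative integer or `NA`.
#' @param tnm_stage Opaque grouping key used for modal tumor-size
#'   imputation, or `NA`.
#' @param tumor_size_cm Tumor size at diagnosis in cm, or `NA`.
#' @param dfs_event `TRUE` if relapse/death was observed, `FALSE` if
#'   censored event-free, `NA` if unknown.
#' @param followup_days Days from surgery to the event or to the latest
#'   news.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, birth_date, diagnosis_date,
                           surgery_date, visits = list(),
                           molecular_subtype = NA, tumor_grade = NA,
                           n_nodes = NA, tnm_stage = NA, tumor_size_cm = NA,
                           dfs_event = NA, followup_days = NA) {
  diagnosis_date <- as_date(diagnosis_date)
  surgery_date <- as_date(surgery_date)
  if (surgery_date < diagnosis_date) {
    stop_input("surgery_date precedes diagnosis_date for patient %s",
               as.character(patient_id))
  }
  if (!all(vapply(visits, inherits, logical(1), "visit_event"))) {
    stop_input("visits must be visit_event objects")
  }
  if (length(visits) > 1L) {
    ord <- order(vapply(visits, function(v) as.numeric(v$date), numeric(1)))
    visits <- visits[ord]
  }
  if (!is.na(molecular_subtype) &&
      !molecular_subtype %in% molecular_subtypes()) {
    stop_input("unknown molecular subtype `%s`", molecular_subtype)
  }
  structure(
    list(patient_id = as.character(patient_id),
         birth_date = if (is.null(birth_date) || all(is.na(birth_date))) NA
                      else as_date(birth_date),
         diagnosis_date = diagnosis_date, surgery_date = surgery_date,
         visits = visits, molecular_subtype = molecular_subtype,
         tumor_grade = tumor_grade, n_nodes = n_nodes,
         tnm_stage = tnm_stage, tumor_size_cm = tumor_size_cm,
         dfs_event = dfs_event, followup_days = followup_days),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient %s: %d visits, subtype %s, event %s, followup %s d>\n",
              x$patient_id, length(x$visits),
              as.character(x$molecular_subtype),
              as.character(x$dfs_event), as.character(x$followup_days)))
  invisible(x)
}

#' Recognized breast-cancer molecular subtypes
#' @return Character vector of subtype labels.
#' @export
molecular_subtypes <- function() {
  c("Luminal", "TNBC", "HER2+/RH-", "HER2+/RH+")
}

#' Select the tabular history window of a record
#'
#' Keeps visits from six months (182 days) before the diagnosis up to one
#' year (365 days) after the first surgery, preserving order.
#'
#' @param record A [patient_record()] with diagnosis and surgery dates.
#' @param pre_diagnosis_days,post_surgery_days Window bounds in days.
#' @return The record with `visits` restricted to the window (possibly
#'   empty).
#' @export
select_history_window <- function(record, pre_diagnosis_days = 182,
                                  post_surgery_days = 365) {
  lo <- record$diagnosis_date - pre_diagnosis_days
  hi <- record$surgery_date + post_surgery_days
  keep <- vapply(record$visits, function(v) v$date >= lo && v$date <= hi,
                 logical(1))
  record$visits <- record$visits[keep]
  record
}

#' Apply the cohort inclusion filters and label patients
#'
#' Reproduces the study inclusion flow: patients who relapsed before the
#' index date (one year after first surgery) are excluded, as are
#' event-free patients whose latest news precedes the three-year horizon
#' and patients with fewer than `min_visits` visits in the selected
#' history window. Remaining patients are labelled with whether the event
#' occurred within the horizon.
#'
#' @param records List of [patient_record()]s with outcome fields.
#' @param horizon_days Label horizon in days from surgery (default 1095,
#'   i.e. 3 years).
#' @param index_offset_days Index date offset from surgery (default 365).
#' @param min_visits Minimum number of in-window visits (default 3).
#' @return A list with `kept` (records with a `label` field: `TRUE` =
#'   event within horizon, negative DFS status) and `exclusions`, a
#'   data frame of `(patient_id, reason)` with one reason per exclusion
#'   (`pre_index_relapse`, `insufficient_followup`, `too_few_visits`).
#' @export
apply_cohort_filters <- function(records, horizon_days = 1095,
                                 index_offset_days = 365, min_visits = 3) {
  kept <- list()
  excl_id <- character()
  excl_reason <- character()
  for (record in records) {
    event <- isTRUE(record$dfs_event)
    fup <- record$followup_days
    if (is.na(fup)) fup <- -Inf
    reason <- NULL
    windowed <- select_history_window(record)
    if (event && fup < index_offset_days) {
      reason <- "pre_index_relapse"
    } else if (!event && fup < horizon_days) {
      reason <- "insufficient_followup"
    } else if (length(windowed$visits) < min_visits) {
      reason <- "too_few_visits"
    }
    if (is.null(reason)) {
      record$label <- event && record$followup_days <= horizon_days
      kept[[length(kept) + 1L]] <- record
    } else {
      excl_id <- c(excl_id, record$patient_id)
      excl_reason <- c(excl_reason, reason)
    }
  }
  list(kept = kept,
       exclusions = data.frame(patient_id = excl_id, reason = excl_reason,
                               stringsAsFactors = FALSE))
}
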