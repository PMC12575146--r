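#' Export a cohort to plain-text tables
#'
#' Writes three files into `dir`: `patients.csv` (static features and
#' outcomes), `events.csv` (one row per visit with the tabular fields)
#' and `reports.jsonl` (one JSON object per report). Dates are ISO-8601.
#'
#' @param records List of patient records.
#' @param dir Output directory (created if needed).
#' @param marker_specs Marker panel defining the biology columns.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir, marker_specs = default_marker_specs()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id,
               birth_date = as.character(r$birth_date),
               diagnosis_date = as.character(r$diagnosis_date),
               surgery_date = as.character(r$surgery_date),
               molecular_subtype = as.character(r$molecular_subtype),
               tumor_grade = r$tumor_grade, n_nodes = r$n_nodes,
               tnm_stage = as.character(r$tnm_stage),
               tumor_size_cm = r$tumor_size_cm,
               dfs_event = r$dfs_event, followup_days = r$followup_days,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  events <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(r$visits, function(v) {
      bio <- lapply(names(marker_specs), function(m) {
        val <- if (!is.null(v$bio_values)) v$bio_values[[m]] else NULL
        if (is.null(val)) NA_real_ else val
      })
      names(bio) <- paste0("bio_", gsub("[^A-Za-z0-9]", "", names(marker_specs)))
      cbind(data.frame(patient_id = r$patient_id,
                       date = as.character(v$date),
                       department = as.character(v$department),
                       procedure = as.character(v$procedure),
                       therapy = as.character(v$therapy),
                       subtherapy = as.character(v$subtherapy),
                       tumor_size_cm = v$tumor_size_cm,
                       stringsAsFactors = FALSE),
            as.data.frame(bio))
    }))
  }))
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  lines <- unlist(lapply(records, function(r) {
    vapply(Filter(function(v) !is.null(v$report_text) && !is.na(v$report_text),
                  r$visits), function(v) {
      jsonlite::toJSON(list(patient_id = r$patient_id,
                            date = as.character(v$date),
                            department = as.character(v$department),
                            procedure = as.character(v$procedure),
                            text = v$report_text),
                       auto_unbox = TRUE, na = "null")
    }, character(1))
  }))
  writeLines(lines, file.path(dir, "reports.jsonl"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `patients.csv`, `events.csv` and
#'   (optionally) `reports.jsonl`.
#' @param marker_specs Marker panel naming the biology columns.
#' @return List of patient records.
#' @export
read_cohort <- function(dir, marker_specs = default_marker_specs()) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  # reports stack per (patient, date) and are consumed in file order, so
  # several same-day reports reattach to their visits in order
  reports <- new.env(parent = emptyenv())
  rp <- file.path(dir, "reports.jsonl")
  if (file.exists(rp)) {
    for (line in readLines(rp)) {
      obj <- jsonlite::fromJSON(line)
      key <- paste(obj$patient_id, obj$date)
      reports[[key]] <- c(reports[[key]], obj$text)
    }
  }
  bio_cols <- paste0("bio_", gsub("[^A-Za-z0-9]", "", names(marker_specs)))
  lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    ev <- events[events$patient_id == p$patient_id, , drop = FALSE]
    visits <- lapply(seq_len(nrow(ev)), function(j) {
      e <- ev[j, ]
      bio <- stats::setNames(as.list(as.numeric(e[bio_cols])),
                             names(marker_specs))
      bio <- bio[!vapply(bio, is.na, logical(1))]
      key <- paste(p$patient_id, e$date)
      txt <- NA
      if (!is.null(reports[[key]]) && length(reports[[key]]) > 0) {
        txt <- reports[[key]][1]
        reports[[key]] <- reports[[key]][-1]
      }
      visit_event(date = e$date,
                  department = e$department, procedure = e$procedure,
                  therapy = e$therapy, subtherapy = e$subtherapy,
                  bio_values = if (length(bio)) bio else NULL,
                  tumor_size_cm = e$tumor_size_cm,
                  report_text = txt)
    })
    patient_record(
      patient_id = p$patient_id, birth_date = p$birth_date,
      diagnosis_date = p$diagnosis_date, surgery_date = p$surgery_date,
      visits = visits, molecular_subtype = p$molecular_subtype,
      tumor_grade = p$tumor_grade, n_nodes = p$n_nodes,
      tnm_stage = p$tnm_stage, tumor_size_cm = p$tumor_size_cm,
      dfs_event = p$dfs_event, followup_days = p$followup_days
    )
  })
}
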