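#' Biological marker specification
#'
#' Describes one biological laboratory feature: its normal range (used to
#' binarize raw measurements into normal/abnormal tokens) and the divisor
#' used to discretize between-visit differences into delta tokens.
#'
#' @param name Marker identifier, e.g. `"CA15-3"`.
#' @param normal_low,normal_high Bounds of the normal range, in the
#'   marker's measurement units; `normal_low < normal_high`.
#' @param delta_unit_divisor Positive number the raw between-visit
#'   difference is divided by before rounding (default 10).
#' @return An object of class `bio_marker_spec`.
#' @examples
#' leuk <- bio_marker_spec("LEUK", 4, 10)
#' binarize_bio(12, leuk)
#' @export
bio_marker_spec <- function(name, normal_low, normal_high,
                            delta_unit_divisor = 10) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("marker `name` must be a non-empty string")
  }
  if (!is_scalar_number(normal_low) || !is_scalar_number(normal_high) ||
      normal_low >= normal_high) {
    stop_input("marker `%s`: need normal_low < normal_high", name)
  }
  if (!is_scalar_number(delta_unit_divisor) || delta_unit_divisor <= 0) {
    stop_input("marker `%s`: delta_unit_divisor must be > 0", name)
  }
  structure(
    list(name = name, normal_low = normal_low, normal_high = normal_high,
         delta_unit_divisor = delta_unit_divisor),
    class = "bio_marker_spec"
  )
}

#' Reference biological marker panel
#'
#' The five serum/blood-count markers retained after the missingness
#' filter: monocytes (MONO), leukocytes (LEUK), lymphocytes (LYMP),
#' polynuclear neutrophils (PN) and the CA 15-3 tumor marker. Normal
#' ranges are standard adult laboratory reference intervals (counts in
#' 10^9 cells/L, CA 15-3 in kU/L).
#'
#' @return Named list of [bio_marker_spec()] objects.
#' @export
default_marker_specs <- function() {
  specs <- list(
    bio_marker_spec("MONO", 0.2, 1.0),
    bio_marker_spec("LEUK", 4.0, 10.0),
    bio_marker_spec("LYMP", 1.0, 4.0),
    bio_marker_spec("PN", 1.5, 7.0),
    bio_marker_spec("CA15-3", 0.0, 30.0)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Lymph-node stage for the Nottingham Prognostic Index
#'
#' Maps the number of involved lymph nodes to the three-level stage
#' entering the NPI: stage 1 for 0 nodes, stage 2 for 1--3 nodes and
#' stage 3 for more than 3 nodes.
#'
#' @param n_nodes Non-negative integer count of involved nodes.
#' @return Integer stage in `{1, 2, 3}`.
#' @examples
#' compute_node_stage(0)
#' compute_node_stage(2)
#' @export
compute_node_stage <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || is.na(n_nodes) ||
      n_nodes < 0 || n_nodes != as.integer(n_nodes)) {
    stop_input("n_nodes must be a single non-negative integer")
  }
  if (n_nodes == 0) 1L else if (n_nodes <= 3) 2L else 3L
}

#' Nottingham Prognostic Index
#'
#' NPI = 0.2 x tumor size (cm) + tumor grade + lymph-node stage, with the
#' node stage from [compute_node_stage()]. Lower scores carry better
#' prognosis. The returned object also carries Blamey's six-band
#' prognostic group (see [assign_prognostic_group()]).
#'
#' @param tumor_size_cm Non-negative tumor size in centimetres.
#' @param grade Histological grade, 1, 2 or 3.
#' @param n_nodes Non-negative integer count of involved lymph nodes.
#' @return A list of class `npi_result` with elements `npi`, `node_stage`
#'   and `prognostic_group`.
#' @examples
#' compute_npi(2, 2, 2) # NPI 4.4
#' @export
compute_npi <- function(tumor_size_cm, grade, n_nodes) {
  if (missing(tumor_size_cm) || missing(grade) || missing(n_nodes) ||
      is.null(tumor_size_cm) || is.null(grade) || is.null(n_nodes) ||
      anyNA(c(tumor_size_cm, grade, n_nodes))) {
    stop_input(paste("compute_npi requires tumor size, grade and node count;",
                     "impute missing values first (see impute_for_dnpi)"))
  }
  if (!is_scalar_number(tumor_size_cm) || tumor_size_cm < 0) {
    stop_input("tumor_size_cm must be a non-negative number")
  }
  if (!grade %in% c(1, 2, 3)) stop_input("grade must be 1, 2 or 3")
  stage <- compute_node_stage(n_nodes)
  npi <- 0.2 * tumor_size_cm + grade + stage
  structure(
    list(npi = npi, node_stage = stage,
         prognostic_group = assign_prognostic_group(npi)),
    class = "npi_result"
  )
}

#' @export
print.npi_result <- function(x, ...) {
  cat(sprintf("NPI %.2f (node stage %d) -> %s\n",
              x$npi, x$node_stage, x$prognostic_group))
  invisible(x)
}

#' Blamey prognostic group from an NPI value
#'
#' Six bands with upper bounds included in the lower group: Excellent
#' (EPG, NPI <= 2.4), Good (GPG, <= 3.4), Moderate I (MPG I, <= 4.4),
#' Moderate II (MPG II, <= 5.4), Poor (PPG, <= 6.4) and Very Poor
#' (VPPG, > 6.4).
#'
#' @param npi Non-negative NPI value.
#' @return One of `"EPG"`, `"GPG"`, `"MPG I"`, `"MPG II"`, `"PPG"`,
#'   `"VPPG"`.
#' @export
assign_prognostic_group <- function(npi) {
  if (!is_scalar_number(npi) || npi < 0) {
    stop_input("npi must be a single non-negative number")
  }
  if (npi <= 2.4) "EPG"
  else if (npi <= 3.4) "GPG"
  else if (npi <= 4.4) "MPG I"
  else if (npi <= 5.4) "MPG II"
  else if (npi <= 6.4) "PPG"
  else "VPPG"
}

#' Ordered prognostic group labels, best to worst
#' @return Character vector of the six group labels.
#' @export
prognostic_group_levels <- function() {
  c("EPG", "GPG", "MPG I", "MPG II", "PPG", "VPPG")
}

#' Impute the inputs of the dynamic NPI
#'
#' Missing node counts are set to zero and missing grades to 2 (the most
#' frequent values); a missing tumor size is replaced by the modal size
#' among cohort members sharing the record's TNM stage. At least one of
#' the three inputs must be observed, otherwise the dynamic NPI is
#' declared unavailable and `NULL` is returned (the trajectory simply
#' skips the token).
#'
#' @param record A [patient_record()].
#' @param cohort List of patient records used to pool tumor sizes by TNM
#'   stage for modal imputation.
#' @return A list `(tumor_size_cm, grade, n_nodes)` or `NULL` when the
#'   dynamic NPI cannot be computed.
#' @export
impute_for_dnpi <- function(record, cohort = list()) {
  size <- record$tumor_size_cm
  grade <- record$tumor_grade
  nodes <- record$n_nodes
  has <- c(size = !is.null(size) && !is.na(size),
           grade = !is.null(grade) && !is.na(grade),
           nodes = !is.null(nodes) && !is.na(nodes))
  if (!any(has)) return(NULL)
  if (!has[["nodes"]]) nodes <- 0L
  if (!has[["grade"]]) grade <- 2L
  if (!has[["size"]]) {
    tnm <- record$tnm_stage
    if (is.null(tnm) || is.na(tnm)) return(NULL)
    peer_sizes <- unlist(lapply(cohort, function(r) {
      if (identical(r$tnm_stage, tnm) &&
          !is.null(r$tumor_size_cm) && !is.na(r$tumor_size_cm)) {
        r$tumor_size_cm
      } else {
        NULL
      }
    }))
    if (length(peer_sizes) == 0L) return(NULL)
    tab <- table(peer_sizes)
    size <- as.numeric(names(tab)[which.max(tab)])
  }
  list(tumor_size_cm = size, grade = as.integer(grade),
       n_nodes = as.integer(nodes))
}

#' Binarize a biological measurement against its normal range
#'
#' Returns token value 1 when the measurement lies outside the marker's
#' normal range and 2 otherwise; the closed boundaries count as normal.
#'
#' @param value Measurement in the marker's units; `NA` yields `NA`
#'   (no token emitted).
#' @param spec A [bio_marker_spec()].
#' @return `1L`, `2L`, or `NA_integer_` for a missing measurement.
#' @export
binarize_bio <- function(value, spec) {
  stopifnot(inherits(spec, "bio_marker_spec"))
  if (is.null(value) || is.na(value)) return(NA_integer_)
  if (value < spec$normal_low || value > spec$normal_high) 1L else 2L
}

#' Delta token for consecutive biological measurements
#'
#' The between-visit difference is divided by the marker's divisor
#' (reference: ten) and rounded half away from zero. A zero token is not
#' emitted (an unchanged measurement carries no information and would
#' crowd the 512-token budget), and the first observation of a marker has
#' no delta.
#'
#' @param v_t Current measurement.
#' @param v_prev Previous measurement of the same marker, or `NA`.
#' @param spec A [bio_marker_spec()].
#' @return Integer token, or `NA_integer_` when absent (no previous
#'   value, missing value, or zero delta).
#' @export
delta_token <- function(v_t, v_prev, spec) {
  stopifnot(inherits(spec, "bio_marker_spec"))
  if (is.null(v_t) || is.na(v_t) || is.null(v_prev) || is.na(v_prev)) {
    return(NA_integer_)
  }
  tok <- as.integer(round_half_away((v_t - v_prev) / spec$delta_unit_divisor))
  if (tok == 0L) NA_integer_ else tok
}

#' Age at a visit, rounded to the nearest integer year
#'
#' @param birth_date,visit_date Dates (or strings coercible to dates),
#'   `visit_date >= birth_date`.
#' @return Integer age in years, or `NA_integer_` if the birth date is
#'   missing.
#' @export
discretize_age <- function(birth_date, visit_date) {
  if (is.null(birth_date) || (length(birth_date) == 1L && is.na(birth_date))) {
    return(NA_integer_)
  }
  birth_date <- as_date(birth_date)
  visit_date <- as_date(visit_date)
  if (visit_date < birth_date) stop_input("visit_date precedes birth_date")
  as.integer(round_half_away(as.numeric(visit_date - birth_date) / 365.25))
}

#' Delay-bucket labels
#'
#' Week buckets W0--W3, month buckets M1--M12, and LT for gaps of a year
#' or more.
#' @return Character vector of the 17 bucket labels in temporal order.
#' @export
delay_bucket_levels <- function() {
  c(paste0("W", 0:3), paste0("M", 1:12), "LT")
}

#' Discretize an inter-visit delay into a bucket
#'
#' Gaps under four weeks map to week buckets (`W0`--`W3`, 7-day weeks);
#' gaps from 28 days to under a year map to month buckets
#' `M1`--`M12` with `M_k = min(12, ceiling(days / 30))`; gaps of 365 days
#' or more map to `LT`. Every non-negative day count falls in exactly one
#' bucket.
#'
#' @param days Non-negative integer number of days.
#' @return Bucket label, one of [delay_bucket_levels()].
#' @examples
#' discretize_delay(5)   # "W0"
#' discretize_delay(100) # "M4"
#' discretize_delay(400) # "LT"
#' @export
discretize_delay <- function(days) {
  if (!is_scalar_number(days) || days < 0) {
    stop_input("days must be a single non-negative number")
  }
  if (days < 28) {
    paste0("W", floor(days / 7))
  } else if (days < 365) {
    paste0("M", min(12, ceiling(days / 30)))
  } else {
    "LT"
  }
}

#' Filter biological markers by cohort-level missingness
#'
#' Keeps the markers whose fraction of missing measurements is below
#' `max_missing` (default 30%). Missingness is computed over the visits
#' at which a biology panel was drawn (visits with at least one
#' biological measurement); visits with no laboratory work at all do not
#' count as missing slots.
#'
#' @param cohort Non-empty list of [patient_record()]s.
#' @param specs Named list of candidate [bio_marker_spec()]s.
#' @param max_missing Exclusive missingness threshold in `(0, 1]`.
#' @return The retained subset of `specs`, with a `missingness` attribute
#'   giving the per-marker missing fraction.
#' @export
filter_bio_features <- function(cohort, specs = default_marker_specs(),
                                max_missing = 0.30) {
  if (length(cohort) == 0L) stop_input("cohort is empty")
  marker_names <- names(specs)
  n_slots <- 0L
  n_obs <- stats::setNames(numeric(length(marker_names)), marker_names)
  for (record in cohort) {
    for (visit in record$visits) {
      bv <- visit$bio_values
      if (is.null(bv) || !any(!is.na(unlist(bv)))) next
      n_slots <- n_slots + 1L
      for (m in marker_names) {
        if (!is.null(bv[[m]]) && !is.na(bv[[m]])) {
          n_obs[[m]] <- n_obs[[m]] + 1
        }
      }
    }
  }
  if (n_slots == 0L) stop_input("cohort has no visits with biology panels")
  missingness <- 1 - n_obs / n_slots
  kept <- specs[missingness < max_missing]
  attr(kept, "missingness") <- missingness
  kept
}

#' Normalize a department or procedure label
#'
#' Lowercases, strips accents, punctuation and special characters, merges
#' synonyms through `synonym_map`, and drops labels whose canonical form
#' appears fewer than `min_count` times in the whole corpus.
#'
#' @param raw Raw label string (or `NA`).
#' @param synonym_map Named character vector mapping variant spellings to
#'   their canonical form (applied after accent/punctuation stripping).
#' @param corpus_counts Named integer vector of canonical-form counts over
#'   the whole cohort; `NULL` disables the frequency filter.
#' @param min_count Minimum corpus count to retain a label (default 100).
#' @return Canonical token, or `NA_character_` when absent.
#' @export
normalize_label <- function(raw, synonym_map = character(),
                            corpus_counts = NULL, min_count = 100L) {
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw))) {
    return(NA_character_)
  }
  tok <- strip_text(raw)
  tok <- gsub("\\s+", " ", trimws(tok))
  if (!nzchar(tok)) return(NA_character_)
  if (tok %in% names(synonym_map)) tok <- unname(synonym_map[[tok]])
  if (!is.null(corpus_counts)) {
    cnt <- corpus_counts[tok]
    if (is.na(cnt) || cnt < min_count) return(NA_character_)
  }
  tok
}

# Lowercase, transliterate accented Latin-1 letters and replace anything
# that is not [a-z0-9 ] by a space. An explicit character map is used
# rather than iconv() so behaviour is identical across locales.
strip_text <- function(x) {
  x <- tolower(x)
  from <- "àáâãäåçèéêëìíîïñòóôõöùúûüý"
  to <- "aaaaaaceeeeiiiinooooouuuuy"
  x <- chartr(from, to, x)
  gsub("[^a-z0-9 ]", " ", x)
}
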