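#' Special tokens and their reserved ids
#' @return Named integer vector: PAD, CLS, SEP, MASK, UNK.
#' @export
special_tokens <- function() {
  c(PAD = 1L, CLS = 2L, SEP = 3L, MASK = 4L, UNK = 5L)
}

#' Modality labels of the tabular trajectory
#'
#' One modality per feature name (the modality layer encodes the feature
#' each token instantiates, which is what allows missing features to be
#' skipped), plus `"special"` for CLS/SEP/PAD/MASK.
#'
#' @param marker_names Character vector of biological marker names.
#' @return Character vector of modality labels.
#' @export
modality_levels <- function(marker_names = names(default_marker_specs())) {
  c("special",
    paste0("bio:", marker_names),
    paste0("delta:", marker_names),
    "department", "procedure", "therapy", "subtherapy",
    "age", "dnpi", "subtype")
}

#' Build a vocabulary from tokenized trajectories
#'
#' Assigns dense integer ids: the five special tokens first, then content
#' tokens sorted lexicographically for reproducibility. Unseen tokens map
#' to `UNK` at encoding time.
#'
#' @param trajectories List of trajectories from [build_trajectory()]
#'   (token strings), typically the training cohort only.
#' @param marker_names Marker names defining the modality layer.
#' @return An object of class `vocabulary` with `token_ids`,
#'   `modality_ids` and `delay_ids` maps.
#' @export
build_vocabulary <- function(trajectories,
                             marker_names = names(default_marker_specs())) {
  specials <- special_tokens()
  content <- sort(unique(unlist(lapply(trajectories, function(tr) {
    tr$tokens[!tr$tokens %in% names(specials)]
  }))))
  token_ids <- c(specials,
                 stats::setNames(seq_along(content) + length(specials),
                                 content))
  mods <- modality_levels(marker_names)
  delays <- delay_bucket_levels()
  structure(
    list(token_ids = token_ids,
         modality_ids = stats::setNames(seq_along(mods), mods),
         delay_ids = stats::setNames(seq_along(delays), delays),
         marker_names = marker_names),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens (%d special), %d modalities, %d delay buckets>\n",
              length(x$token_ids), length(special_tokens()),
              length(x$modality_ids), length(x$delay_ids)))
  invisible(x)
}

#' Content (non-special) token ids of a vocabulary
#' @param vocab A [build_vocabulary()] object.
#' @return Integer vector of content token ids.
#' @export
content_token_ids <- function(vocab) {
  unname(vocab$token_ids[!names(vocab$token_ids) %in%
                           names(special_tokens())])
}

#' Tokenize one visit into (token, modality) pairs
#'
#' Emits, in a fixed canonical order: up to five binarized biological
#' marker tokens, up to five marker delta tokens, department, procedure,
#' therapy, subtherapy, age, the dynamic-NPI prognostic-group token and
#' the molecular subtype -- at most 17 pairs with the five-marker panel.
#' Missing features are skipped; a zero biological delta emits nothing.
#'
#' @param visit A [visit_event()].
#' @param context List carrying `marker_specs`, `prev_bio` (named numeric
#'   vector of the previous observation of each marker), `birth_date`,
#'   `subtype` and `dnpi_group` (current prognostic-group label or `NA`).
#' @return Data frame with columns `token` and `modality` (0--17 rows).
#' @export
tokenize_visit <- function(visit, context) {
  specs <- context$marker_specs
  tokens <- character()
  mods <- character()
  add <- function(token, modality) {
    tokens[[length(tokens) + 1L]] <<- token
    mods[[length(mods) + 1L]] <<- modality
  }
  bv <- visit$bio_values
  for (m in names(specs)) {
    val <- if (!is.null(bv)) bv[[m]] else NULL
    b <- binarize_bio(if (is.null(val)) NA else val, specs[[m]])
    if (!is.na(b)) add(sprintf("bio:%s=%d", m, b), paste0("bio:", m))
  }
  for (m in names(specs)) {
    val <- if (!is.null(bv)) bv[[m]] else NULL
    prev <- context$prev_bio[[m]] %||% NA
    d <- delta_token(if (is.null(val)) NA else val, prev, specs[[m]])
    if (!is.na(d)) add(sprintf("delta:%s=%+d", m, d), paste0("delta:", m))
  }
  if (!is.na(visit$department)) add(paste0("dept:", visit$department), "department")
  if (!is.na(visit$procedure)) add(paste0("proc:", visit$procedure), "procedure")
  if (!is.na(visit$therapy)) add(paste0("ther:", visit$therapy), "therapy")
  if (!is.na(visit$subtherapy)) add(paste0("subther:", visit$subtherapy), "subtherapy")
  age <- discretize_age(context$birth_date, visit$date)
  if (!is.na(age)) add(paste0("age:", age), "age")
  if (!is.null(context$dnpi_group) && !is.na(context$dnpi_group)) {
    add(paste0("pg:", context$dnpi_group), "dnpi")
  }
  if (!is.null(context$subtype) && !is.na(context$subtype)) {
    add(paste0("subtype:", context$subtype), "subtype")
  }
  data.frame(token = tokens, modality = mods, stringsAsFactors = FALSE)
}

#' Build the tabular trajectory of one patient
#'
#' Produces the four aligned layers of the tabular model input: token,
#' modality, delay bucket and position. The sequence starts with `CLS`;
#' each visit's tokens are followed by a `SEP` (including the last
#' visit). Every token of a visit carries the visit's delay bucket (the
#' discretized gap to the previous visit; first visit and `CLS` carry
#' `W0`). The prognostic-group token is recomputed whenever a new tumor
#' size is observed and carried forward between measurements. The
#' sequence is truncated to its first `max_len` entries.
#'
#' @param record A [patient_record()] whose visits are already restricted
#'   to the history window.
#' @param marker_specs Named list of [bio_marker_spec()]s.
#' @param cohort Optional list of records used for dNPI imputation.
#' @param max_len Maximum sequence length (default 512).
#' @return An object of class `tokenized_trajectory` with character
#'   layers `tokens`, `modalities`, `delays`, integer `positions`
#'   (0-based), and the `label` if present.
#' @export
build_trajectory <- function(record, marker_specs = default_marker_specs(),
                             cohort = list(), max_len = 512L) {
  if (length(record$visits) == 0L) {
    stop_input("patient %s has no visits in the selected window",
               record$patient_id)
  }
  imput <- impute_for_dnpi(record, cohort)
  dnpi_group <- NA_character_
  if (!is.null(imput)) {
    dnpi_group <- compute_npi(imput$tumor_size_cm, imput$grade,
                              imput$n_nodes)$prognostic_group
  }
  tokens <- "CLS"; mods <- "special"; delays <- "W0"
  prev_bio <- list()
  prev_date <- NULL
  for (visit in record$visits) {
    gap <- if (is.null(prev_date)) 0 else as.numeric(visit$date - prev_date)
    bucket <- discretize_delay(gap)
    prev_date <- visit$date
    if (!is.na(visit$tumor_size_cm) && !is.null(imput)) {
      dnpi_group <- compute_npi(visit$tumor_size_cm, imput$grade,
                                imput$n_nodes)$prognostic_group
    }
    ctx <- list(marker_specs = marker_specs, prev_bio = prev_bio,
                birth_date = record$birth_date,
                subtype = record$molecular_subtype, dnpi_group = dnpi_group)
    pairs <- tokenize_visit(visit, ctx)
    bv <- visit$bio_values
    if (!is.null(bv)) {
      for (m in names(marker_specs)) {
        if (!is.null(bv[[m]]) && !is.na(bv[[m]])) prev_bio[[m]] <- bv[[m]]
      }
    }
    tokens <- c(tokens, pairs$token, "SEP")
    mods <- c(mods, pairs$modality, "special")
    delays <- c(delays, rep(bucket, nrow(pairs) + 1L))
  }
  n <- min(length(tokens), max_len)
  structure(
    list(tokens = tokens[seq_len(n)], modalities = mods[seq_len(n)],
         delays = delays[seq_len(n)], positions = seq_len(n) - 1L,
         label = record$label %||% NA, patient_id = record$patient_id),
    class = "tokenized_trajectory"
  )
}

#' @export
print.tokenized_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d tokens, %d visits, label %s>\n",
              x$patient_id %||% "?", length(x$tokens),
              sum(x$tokens == "SEP"), as.character(x$label)))
  invisible(x)
}

#' Encode a string trajectory into integer id layers
#'
#' Maps the token/modality/delay layers of a trajectory through a
#' vocabulary; tokens unseen at vocabulary-building time become `UNK`.
#'
#' @param traj A [build_trajectory()] result.
#' @param vocab A [build_vocabulary()] object.
#' @return The trajectory with integer layers `token_ids`,
#'   `modality_ids`, `delay_ids` added.
#' @export
encode_trajectory <- function(traj, vocab) {
  ids <- vocab$token_ids[traj$tokens]
  ids[is.na(ids)] <- special_tokens()[["UNK"]]
  mod_ids <- vocab$modality_ids[traj$modalities]
  if (anyNA(mod_ids)) stop_input("trajectory contains an unknown modality")
  del_ids <- vocab$delay_ids[traj$delays]
  if (anyNA(del_ids)) stop_input("trajectory contains an unknown delay bucket")
  traj$token_ids <- unname(ids)
  traj$modality_ids <- unname(mod_ids)
  traj$delay_ids <- unname(del_ids)
  traj
}

#' Tokenize and encode a whole cohort
#'
#' Convenience wrapper: selects each record's history window, builds the
#' string trajectories, fits a vocabulary on them (or reuses a supplied
#' one) and encodes all trajectories.
#'
#' @param records List of labelled [patient_record()]s.
#' @param marker_specs Named list of [bio_marker_spec()]s.
#' @param vocab Optional existing vocabulary (e.g. from a training
#'   cohort); built from `records` when `NULL`.
#' @param max_len Maximum sequence length.
#' @return List with `trajectories` (encoded) and `vocab`.
#' @export
tokenize_cohort <- function(records, marker_specs = default_marker_specs(),
                            vocab = NULL, max_len = 512L) {
  windowed <- lapply(records, select_history_window)
  trajs <- lapply(windowed, build_trajectory, marker_specs = marker_specs,
                  cohort = records, max_len = max_len)
  if (is.null(vocab)) {
    vocab <- build_vocabulary(trajs, marker_names = names(marker_specs))
  }
  list(trajectories = lapply(trajs, encode_trajectory, vocab = vocab),
       vocab = vocab)
}

#' Serialize trajectories to JSON lines
#'
#' One JSON object per line with the id layers, position layer, label and
#' patient id; [read_trajectories_jsonl()] reproduces identical id
#' sequences.
#'
#' @param trajectories List of encoded trajectories.
#' @param path Output file path.
#' @export
write_trajectories_jsonl <- function(trajectories, path) {
  lines <- vapply(trajectories, function(tr) {
    jsonlite::toJSON(list(
      patient_id = tr$patient_id %||% NA,
      token_ids = tr$token_ids, modality_ids = tr$modality_ids,
      delay_ids = tr$delay_ids, positions = tr$positions,
      tokens = tr$tokens, modalities = tr$modalities, delays = tr$delays,
      label = tr$label
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
}

#' Read trajectories written by [write_trajectories_jsonl()]
#' @param path Input file path.
#' @return List of `tokenized_trajectory` objects.
#' @export
read_trajectories_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line)
    structure(
      list(tokens = obj$tokens, modalities = obj$modalities,
           delays = obj$delays, positions = as.integer(obj$positions),
           label = if (is.null(obj$label)) NA else obj$label,
           patient_id = if (is.null(obj$patient_id)) NA else obj$patient_id,
           token_ids = as.integer(obj$token_ids),
           modality_ids = as.integer(obj$modality_ids),
           delay_ids = as.integer(obj$delay_ids)),
      class = "tokenized_trajectory"
    )
  })
}

#' Write a vocabulary to JSON
#' @param vocab A [build_vocabulary()] object.
#' @param path Output file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(token_ids = as.list(vocab$token_ids),
         modality_ids = as.list(vocab$modality_ids),
         delay_ids = as.list(vocab$delay_ids),
         marker_names = vocab$marker_names),
    path, auto_unbox = TRUE
  )
}

#' Read a vocabulary written by [write_vocabulary()]
#' @param path Input file path.
#' @return A `vocabulary` object.
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(
    list(token_ids = unlist(obj$token_ids),
         modality_ids = unlist(obj$modality_ids),
         delay_ids = unlist(obj$delay_ids),
         marker_names = obj$marker_names),
    class = "vocabulary"
  )
}
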