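#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with the standard tie correction;
#' equivalent to the trapezoidal area under the empirical ROC curve and
#' invariant under strictly increasing score transforms.
#'
#' @param labels Logical/0-1 outcome labels; both classes required.
#' @param scores Numeric risk scores (higher = higher predicted risk).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop_input("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a class-stratified percentile bootstrap interval
#'
#' @param labels,scores As in [roc_auc()].
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Optional seed.
#' @param conf Confidence level (default 0.95).
#' @param subgroup Label stored in the report (default `"all"`).
#' @return A one-row data frame of class `eval_report`: `metric`,
#'   `estimate`, `lower`, `upper`, `n`, `subgroup`.
#' @export
roc_auc_ci <- function(labels, scores, n_boot = 2000, seed = NULL,
                       conf = 0.95, subgroup = "all") {
  labels <- as.logical(labels)
  est <- roc_auc(labels, scores)
  pos <- which(labels)
  neg <- which(!labels)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    roc_auc(labels[idx], scores[idx])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  out <- data.frame(metric = "auc_roc", estimate = est, lower = qs[1],
                    upper = qs[2], n = length(labels), subgroup = subgroup,
                    stringsAsFactors = FALSE)
  class(out) <- c("eval_report", class(out))
  out
}

#' Average precision score
#'
#' Step-wise integral of the precision-recall curve,
#' `AP = sum_k (R_k - R_{k-1}) P_k` over distinct score thresholds in
#' decreasing order; the model-selection criterion used for all
#' classifiers.
#'
#' @param labels,scores As in [roc_auc()].
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L || n1 == length(labels)) {
    stop_input("both classes must be present")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels & sel)
    precision <- tp / sum(sel)
    recall <- tp / n1
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' DeLong test for paired AUC comparison
#'
#' Nonparametric test of equality of two correlated AUCs computed on the
#' same samples, via placement values: the covariance of the paired
#' placement structures estimates the variance of the AUC difference and
#' a two-sided normal p-value is returned.
#'
#' @param labels Shared outcome labels.
#' @param scores_a,scores_b Paired prediction scores of the two models.
#' @return List with `auc_a`, `auc_b`, `statistic` (z), `p_value`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- as.logical(labels)
  pos <- which(labels)
  neg <- which(!labels)
  m <- length(pos)
  n <- length(neg)
  if (m == 0L || n == 0L) stop_input("both classes must be present")
  placements <- function(s) {
    xp <- s[pos]
    xn <- s[neg]
    v10 <- vapply(xp, function(x) mean((x > xn) + 0.5 * (x == xn)),
                  numeric(1))
    v01 <- vapply(xn, function(y) mean((xp > y) + 0.5 * (xp == y)),
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  dauc <- pa$auc - pb$auc
  if (var_diff < 1e-16) {
    if (abs(dauc) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, statistic = 0,
                  p_value = 1))
    }
    stop_input("degenerate DeLong variance with unequal AUCs")
  }
  z <- dauc / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Nottingham Prognostic Index baseline scores
#'
#' The clinical baseline: each patient's risk score is the NPI computed
#' from diagnosis-time tumor size, grade and node count, after the
#' standard imputations. Higher NPI means higher predicted risk.
#'
#' @param records List of patient records.
#' @return Numeric scores (`NA` where the NPI is unavailable).
#' @export
npi_baseline_scores <- function(records) {
  vapply(records, function(r) {
    imput <- impute_for_dnpi(r, records)
    if (is.null(imput)) return(NA_real_)
    compute_npi(imput$tumor_size_cm, imput$grade, imput$n_nodes)$npi
  }, numeric(1))
}

#' Subgroup-stratified evaluation
#'
#' One AUC report per stratum; strata with fewer than `min_per_class`
#' samples of either class are flagged `insufficient` rather than
#' scored.
#'
#' @param labels,scores As in [roc_auc()].
#' @param strata Stratum label per patient (age band, grade, subtype,
#'   node status, ...).
#' @param min_per_class Minimum per-class count to score a stratum.
#' @param n_boot,seed Bootstrap settings for the intervals.
#' @return Data frame with one row per stratum (`eval_report` rows plus
#'   a `status` column).
#' @export
stratified_eval <- function(labels, scores, strata, min_per_class = 5,
                            n_boot = 2000, seed = NULL) {
  labels <- as.logical(labels)
  out <- lapply(unique(strata), function(s) {
    sel <- strata == s
    n1 <- sum(labels[sel])
    n0 <- sum(!labels[sel])
    if (n1 < min_per_class || n0 < min_per_class) {
      data.frame(metric = "auc_roc", estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, n = sum(sel), subgroup = s,
                 status = "insufficient", stringsAsFactors = FALSE)
    } else {
      rep <- roc_auc_ci(labels[sel], scores[sel], n_boot = n_boot,
                        seed = seed, subgroup = s)
      rep$status <- "ok"
      rep
    }
  })
  do.call(rbind, out)
}

#' Random search over a configuration grid
#'
#' Replaces automated hyperparameter optimization with an explicit,
#' reproducible draw: each candidate samples one value per grid entry.
#'
#' @param grid Named list of candidate value vectors (e.g.
#'   `list(learning_rate = c(1e-3, 5e-4), n_layers = 2:4)`).
#' @param n_draws Number of candidate configurations.
#' @param seed Sampling seed.
#' @return List of named lists, one per candidate.
#' @export
random_search_configs <- function(grid, n_draws, seed = 1) {
  with_seed(seed, lapply(seq_len(n_draws), function(i) {
    lapply(grid, function(vals) vals[[sample.int(length(vals), 1)]])
  }))
}

#' Select a model by validation average precision
#'
#' The model-selection criterion for all classifiers: among candidate
#' score vectors on a common validation set, pick the one with the
#' highest average precision.
#'
#' @param labels Validation labels.
#' @param scores_list List of score vectors, one per candidate.
#' @return List with `best` (index), `aps` (per-candidate scores).
#' @export
select_by_average_precision <- function(labels, scores_list) {
  aps <- vapply(scores_list, function(s) average_precision(labels, s),
                numeric(1))
  list(best = which.max(aps), aps = aps)
}

#' Flatten a patient record into static count features
#'
#' The representation used by non-sequential baselines: department,
#' procedure and therapy occurrence counts over the history window,
#' abnormal-measurement counts per marker, and diagnosis-time clinical
#' features (missing values coded 999).
#'
#' @param records Labelled patient records.
#' @param marker_specs Marker panel.
#' @return Data frame, one row per patient, plus a `label` column.
#' @export
flatten_features <- function(records, marker_specs = default_marker_specs()) {
  windowed <- lapply(records, select_history_window)
  depts <- sort(unique(unlist(lapply(windowed, function(r) {
    vapply(r$visits, function(v) as.character(v$department), character(1))
  }))))
  procs <- sort(unique(unlist(lapply(windowed, function(r) {
    vapply(r$visits, function(v) as.character(v$procedure), character(1))
  }))))
  depts <- depts[!is.na(depts)]
  procs <- procs[!is.na(procs)]
  rows <- lapply(windowed, function(r) {
    dv <- vapply(r$visits, function(v) as.character(v$department), character(1))
    pv <- vapply(r$visits, function(v) as.character(v$procedure), character(1))
    abn <- vapply(names(marker_specs), function(m) {
      sum(vapply(r$visits, function(v) {
        val <- if (!is.null(v$bio_values)) v$bio_values[[m]] else NULL
        identical(binarize_bio(if (is.null(val)) NA else val,
                               marker_specs[[m]]), 1L)
      }, logical(1)))
    }, numeric(1))
    age <- discretize_age(r$birth_date, r$diagnosis_date)
    c(stats::setNames(vapply(depts, function(d) sum(dv == d, na.rm = TRUE),
                             numeric(1)), paste0("dept_", seq_along(depts))),
      stats::setNames(vapply(procs, function(p) sum(pv == p, na.rm = TRUE),
                             numeric(1)), paste0("proc_", seq_along(procs))),
      stats::setNames(abn, paste0("abn_", seq_along(abn))),
      age = if (is.na(age)) 999 else age,
      size = if (is.na(r$tumor_size_cm)) 999 else r$tumor_size_cm,
      grade = if (is.na(r$tumor_grade)) 999 else r$tumor_grade,
      nodes = if (is.na(r$n_nodes)) 999 else r$n_nodes,
      tnbc = identical(r$molecular_subtype, "TNBC") + 0)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- vapply(records, function(r) isTRUE(r$label), logical(1))
  out
}

#' Learning-curve comparison against a flat-feature baseline
#'
#' For each training-set size and seed, fine-tunes the pretrained
#' trajectory classifier on a stratified subsample and fits a logistic
#' regression on flattened count features, evaluating both on a common
#' held-out set. Quantifies how the pretrained sequence model's
#' advantage depends on the amount of labelled data.
#'
#' @param pretrained An `mlm_model`.
#' @param trajectories Encoded labelled trajectories (training pool).
#' @param records Matching patient records (same order).
#' @param test_trajectories,test_records Held-out evaluation set.
#' @param sizes Training-set sizes to probe.
#' @param seeds Seeds (one fine-tuning run per size x seed).
#' @param config [finetune_config()] for the sequence model.
#' @return Data frame `(size, seed, auc_sequence, auc_flat, advantage)`.
#' @export
learning_curve <- function(pretrained, trajectories, records,
                           test_trajectories, test_records,
                           sizes = c(10, 50, 250), seeds = 1:3,
                           config = finetune_config()) {
  labels <- vapply(trajectories, function(tr) isTRUE(tr$label), logical(1))
  test_labels <- vapply(test_trajectories, function(tr) isTRUE(tr$label),
                        logical(1))
  flat_all <- flatten_features(c(records, test_records))
  flat_train <- flat_all[seq_along(records), , drop = FALSE]
  flat_test <- flat_all[length(records) + seq_along(test_records), ,
                        drop = FALSE]
  out <- list()
  for (size in sizes) {
    for (seed in seeds) {
      idx <- with_seed(seed, {
        pos <- which(labels)
        neg <- which(!labels)
        n_pos <- max(2L, round(size * mean(labels)))
        n_pos <- min(n_pos, size - 2L, length(pos))
        c(pos[sample.int(length(pos), n_pos)],
          neg[sample.int(length(neg), min(size - n_pos, length(neg)))])
      })
      cfg <- config
      cfg$seed <- seed
      clf <- finetune_tabular(pretrained, trajectories[idx], cfg)
      p_seq <- predict_proba(clf, test_trajectories)
      fit <- suppressWarnings(stats::glm(
        label ~ ., data = flat_train[idx, , drop = FALSE],
        family = stats::binomial()))
      p_flat <- suppressWarnings(
        stats::predict(fit, newdata = flat_test, type = "response"))
      auc_seq <- roc_auc(test_labels, p_seq)
      auc_flat <- roc_auc(test_labels, p_flat)
      out[[length(out) + 1L]] <- data.frame(
        size = size, seed = seed, auc_sequence = auc_seq,
        auc_flat = auc_flat, advantage = auc_seq - auc_flat)
    }
  }
  do.call(rbind, out)
}
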