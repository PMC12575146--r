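#' Integrated gradients along a straight-line path
#'
#' Path-integral attribution: for a differentiable scalar function `F`,
#' the attribution of input component i is
#' `(x_i - x'_i) * integral_0^1 dF/dx_i (x' + a (x - x')) da`,
#' approximated with a midpoint Riemann sum over `steps` interpolation
#' points. The completeness gap `|sum(attributions) - (F(x) - F(x'))|`
#' is always reported, never hidden; it shrinks as `steps` grows.
#'
#' @param f Function taking an input matrix and returning
#'   `list(value = scalar, grad = matrix like x)`.
#' @param x Input matrix (positions x embedding dimensions).
#' @param baseline Baseline matrix of the same shape.
#' @param steps Number of interpolation points (>= 1).
#' @return An object of class `attribution_result`: `attributions`
#'   (matrix like `x`), `scores` (per-position row sums), `value`,
#'   `baseline_value` and `completeness_gap`.
#' @export
integrated_gradients <- function(f, x, baseline, steps = 200) {
  if (steps < 1) stop_input("steps must be >= 1")
  x <- as.matrix(x)
  baseline <- as.matrix(baseline)
  if (!all(dim(x) == dim(baseline))) {
    stop_input("baseline must have the same shape as the input")
  }
  diff <- x - baseline
  avg_grad <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    avg_grad <- avg_grad + f(baseline + alpha * diff)$grad
  }
  avg_grad <- avg_grad / steps
  attributions <- diff * avg_grad
  v1 <- f(x)$value
  v0 <- f(baseline)$value
  structure(
    list(attributions = attributions, scores = rowSums(attributions),
         value = v1, baseline_value = v0,
         completeness_gap = abs(sum(attributions) - (v1 - v0))),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution: %d positions, F(x)=%.4f, F(x')=%.4f, completeness gap %.2e>\n",
              length(x$scores), x$value, x$baseline_value,
              x$completeness_gap))
  invisible(x)
}

#' Integrated gradients for the tabular classifier
#'
#' Attributes the predicted event probability of one trajectory to its
#' token positions. The input is the summed input embedding; the default
#' baseline replaces every token by `PAD` (special modality, `W0` delay,
#' positions kept), so attributions measure what each observed token
#' contributes relative to an empty trajectory.
#'
#' @param model A `tabular_classifier`.
#' @param traj One encoded trajectory.
#' @param steps Interpolation points (default 200).
#' @param baseline Optional explicit baseline embedding matrix.
#' @return An `attribution_result` with one score per token position and
#'   the trajectory's tokens/modalities attached.
#' @export
ig_tabular <- function(model, traj, steps = 200, baseline = NULL) {
  params <- model$params
  cfg <- model$config
  batch <- pack_batch(list(traj))
  X <- embed_tabular(params, batch)
  if (is.null(baseline)) {
    sp <- special_tokens()
    n <- length(traj$token_ids)
    bbatch <- batch
    bbatch$tok <- rep(sp[["PAD"]], n)
    bbatch$mod <- rep(1L, n)
    bbatch$del <- rep(1L, n)
    baseline <- embed_tabular(params, bbatch)
  }
  f <- function(Xa) {
    fwd <- encoder_forward(params, cfg, Xa, batch$seqs)
    hc <- fwd$H[1, , drop = FALSE]
    p <- sigmoid(drop(hc %*% params$cls_w) + params$cls_b)
    dH <- matrix(0, nrow(Xa), ncol(Xa))
    dH[1, ] <- p * (1 - p) * params$cls_w
    bwd <- encoder_backward(params, cfg, fwd, batch$seqs, dH)
    list(value = p, grad = bwd$dX)
  }
  res <- integrated_gradients(f, X, baseline, steps)
  res$tokens <- traj$tokens
  res$modalities <- traj$modalities
  res
}

#' Integrated gradients for the text classifier
#'
#' Attributes the predicted probability to the patient's reports: the
#' straight-line path interpolates the pooled report vectors between the
#' zero baseline (an empty report) and their observed values, while the
#' learned CLS/SEP vectors and delay/position embeddings stay fixed. One
#' score per report.
#'
#' @param model A `text_classifier`.
#' @param ttraj One report trajectory.
#' @param steps Interpolation points.
#' @return An `attribution_result` with one score per report.
#' @export
ig_text <- function(model, ttraj, steps = 200) {
  params <- model$params
  cfg <- model$config
  batch <- pack_text_batch(list(ttraj), model$delay_ids)
  R <- batch$Rstack
  f <- function(Ra) {
    b <- batch
    b$Rstack <- Ra
    X <- text_input_forward(params, b)
    fwd <- encoder_forward(params, cfg, X, b$seqs)
    hc <- fwd$H[1, , drop = FALSE]
    p <- sigmoid(drop(hc %*% params$cls_w) + params$cls_b)
    dH <- matrix(0, nrow(X), ncol(X))
    dH[1, ] <- p * (1 - p) * params$cls_w
    bwd <- encoder_backward(params, cfg, fwd, b$seqs, dH)
    list(value = p, grad = bwd$dX[b$rep_rows, , drop = FALSE] %*%
           t(params$proj_W))
  }
  integrated_gradients(f, R, R * 0, steps)
}

#' Attribution scores of every report in a cohort
#'
#' Runs [ig_text()] over all patients and collects one row per report.
#'
#' @param model A `text_classifier`.
#' @param text_trajectories List of report trajectories (with labels).
#' @param steps Interpolation points per patient (default 50 for
#'   cohort-scale runs).
#' @return Data frame `(patient_id, report_idx, date, score, label)`.
#' @export
cohort_report_attributions <- function(model, text_trajectories,
                                       steps = 50) {
  out <- lapply(text_trajectories, function(tt) {
    res <- ig_text(model, tt, steps = steps)
    data.frame(patient_id = tt$patient_id %||% NA,
               report_idx = seq_along(res$scores),
               date = tt$dates,
               score = res$scores,
               label = isTRUE(tt$label),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select high-attribution reports per outcome class
#'
#' Splits the cohort's reports by patient outcome and keeps, in each
#' class, the reports whose signed relevance toward that class exceeds a
#' threshold. Relevance toward the event class is the attribution score
#' itself; toward the event-free class it is the negated score. The
#' default threshold is the 95th percentile of relevance within each
#' class.
#'
#' @param attributions Data frame from [cohort_report_attributions()].
#' @param threshold Numeric threshold applied to the signed relevance, or
#'   `NULL` for the per-class 95th percentile.
#' @param quantile_level Percentile used when `threshold` is `NULL`.
#' @return List with `dfs_neg` (reports predictive of the event /
#'   negative DFS status), `dfs_pos`, and the applied `thresholds`.
#' @export
select_high_attribution_reports <- function(attributions, threshold = NULL,
                                            quantile_level = 0.95) {
  pick <- function(df, relevance) {
    thr <- threshold %||% stats::quantile(relevance, quantile_level,
                                          names = FALSE)
    sel <- df[relevance >= thr, , drop = FALSE]
    list(sel = sel, thr = thr)
  }
  neg_df <- attributions[attributions$label, , drop = FALSE]
  pos_df <- attributions[!attributions$label, , drop = FALSE]
  neg <- pick(neg_df, neg_df$score)
  pos <- pick(pos_df, -pos_df$score)
  if (nrow(neg$sel) == 0L && nrow(pos$sel) == 0L) {
    warning("attribution threshold excluded every report")
  }
  list(dfs_neg = neg$sel, dfs_pos = pos$sel,
       thresholds = c(dfs_neg = neg$thr, dfs_pos = pos$thr))
}

ngram_document_counts <- function(texts, n_range, stopwords) {
  env <- new.env(parent = emptyenv())
  for (text in texts) {
    toks <- preprocess_report(text, stopwords)
    seen <- character()
    for (n in n_range) {
      if (length(toks) < n) next
      for (i in seq_len(length(toks) - n + 1L)) {
        phrase <- paste(toks[i:(i + n - 1L)], collapse = " ")
        if (!phrase %in% seen) {
          seen <- c(seen, phrase)
          env[[phrase]] <- (env[[phrase]] %||% 0L) + 1L
        }
      }
    }
  }
  counts <- unlist(as.list(env))
  if (is.null(counts)) counts <- integer()
  counts
}

top_k_phrases <- function(counts, k) {
  if (length(counts) == 0L) return(character())
  ord <- order(-counts, names(counts))
  names(counts)[ord][seq_len(min(k, length(counts)))]
}

merge_overlapping_phrases <- function(phrases) {
  toks <- lapply(phrases, function(p) strsplit(p, " ")[[1]])
  # chain phrases whose suffix overlaps another's prefix by >= 2 tokens
  changed <- TRUE
  while (changed && length(toks) > 1L) {
    changed <- FALSE
    for (i in seq_along(toks)) {
      for (j in seq_along(toks)) {
        if (i == j) next
        a <- toks[[i]]; b <- toks[[j]]
        max_ov <- min(length(a), length(b)) - 1L
        for (ov in rev(seq_len(max_ov))) {
          if (ov < 2L) break
          if (identical(utils::tail(a, ov), utils::head(b, ov))) {
            toks[[i]] <- c(a, utils::tail(b, length(b) - ov))
            toks[[j]] <- NULL
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
      if (changed) break
    }
  }
  phrases <- vapply(toks, paste, character(1), collapse = " ")
  # drop phrases contained in a longer kept phrase
  contained <- vapply(seq_along(phrases), function(i) {
    any(vapply(seq_along(phrases), function(j) {
      i != j && nchar(phrases[j]) > nchar(phrases[i]) &&
        grepl(phrases[i], phrases[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  sort(phrases[!contained])
}

#' Frequent word sequences distinctive of one report collection
#'
#' Counts, for every n-gram length in `n_range` (reference 3--9 words),
#' the number of reports containing each phrase (document frequency,
#' since the downstream survival comparison groups patients by whether a
#' report contains the phrase), takes each group's `top_k` most frequent
#' phrases (ties broken lexicographically), returns the phrases in A's
#' top list absent from B's, and combines overlapping phrases.
#'
#' @param reports_a,reports_b Character vectors of report texts (e.g. the
#'   high-attribution collections for each outcome class).
#' @param n_range Integer n-gram lengths (default `3:9`).
#' @param top_k Top-list size per group (default 30).
#' @param stopwords Stopword list for preprocessing.
#' @return List with `phrases` (merged distinctive phrases of A),
#'   `top_a`, `top_b`, and the full `counts_a`/`counts_b` tables.
#' @export
frequent_sequences <- function(reports_a, reports_b, n_range = 3:9,
                               top_k = 30, stopwords = default_stopwords()) {
  counts_a <- ngram_document_counts(reports_a, n_range, stopwords)
  counts_b <- ngram_document_counts(reports_b, n_range, stopwords)
  top_a <- top_k_phrases(counts_a, top_k)
  top_b <- top_k_phrases(counts_b, top_k)
  distinct <- setdiff(top_a, top_b)
  list(phrases = merge_overlapping_phrases(distinct),
       top_a = top_a, top_b = top_b,
       counts_a = counts_a, counts_b = counts_b)
}
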