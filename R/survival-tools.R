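#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator of the survival function: the curve
#' starts at 1, is non-increasing and right-continuous, stepping at each
#' distinct event time. All-censored input yields a flat curve at 1.
#'
#' @param time Non-negative times to event or censoring (days).
#' @param event Logical/0-1 event indicators.
#' @return Data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor` and `survival` (one row per distinct event
#'   time).
#' @examples
#' km_estimate(c(1, 2), c(TRUE, TRUE))
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop_input("need at least one sample")
  if (any(time < 0)) stop_input("times must be non-negative")
  event <- as.logical(event)
  ts <- sort(unique(time[event]))
  surv <- 1
  rows <- lapply(ts, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    cns <- sum(time == t & !event)
    surv <<- surv * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, n_censor = cns,
               survival = surv)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), survival = numeric())
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km A [km_estimate()] result.
#' @param t Times at which to read the survival probability.
#' @return Numeric survival probabilities (1 before the first event).
#' @export
km_survival <- function(km, t) {
  vapply(t, function(tt) {
    below <- km$time <= tt
    if (!any(below)) 1 else km$survival[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank test comparing observed and
#' expected event counts across the distinct event times of the pooled
#' sample.
#'
#' @param time Times to event or censoring.
#' @param event Logical/0-1 event indicators.
#' @param group Two-level grouping vector (e.g. phrase present/absent).
#' @return List with `statistic` (chi-square), `df` (1), `p_value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop_input("group must have exactly two levels")
  if (any(table(g) == 0L)) stop_input("both groups must be non-empty")
  if (sum(event) == 0L) stop_input("no events; log-rank test undefined")
  is1 <- g == levels(g)[1]
  ts <- sort(unique(time[event]))
  o1 <- 0; e1 <- 0; vsum <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & is1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & is1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      vsum <- vsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (vsum <= 0) {
    if (abs(o1 - e1) < 1e-12) {
      return(list(statistic = 0, df = 1L, p_value = 1,
                  observed = c(o1, sum(event) - o1),
                  expected = c(e1, sum(event) - e1)))
    }
    stop_input("degenerate log-rank variance")
  }
  stat <- (o1 - e1)^2 / vsum
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(o1, sum(event) - o1),
       expected = c(e1, sum(event) - e1))
}

#' Kaplan-Meier / log-rank comparison of patients by phrase presence
#'
#' Groups patients by whether any of their reports contains a phrase
#' (after preprocessing), then compares disease-free survival between
#' the groups.
#'
#' @param records Labelled patient records with report texts.
#' @param phrase Phrase (space-separated preprocessed tokens).
#' @param stopwords Stopword list used for matching.
#' @return List with `km_present`, `km_absent`, `logrank` and the
#'   per-patient `present` indicator.
#' @export
phrase_survival <- function(records, phrase, stopwords = default_stopwords()) {
  present <- vapply(records, function(r) {
    any(vapply(r$visits, function(v) {
      if (is.null(v$report_text) || is.na(v$report_text)) return(FALSE)
      toks <- preprocess_report(v$report_text, stopwords)
      grepl(phrase, paste(toks, collapse = " "), fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  time <- vapply(records, function(r) as.numeric(r$followup_days), numeric(1))
  event <- vapply(records, function(r) isTRUE(r$dfs_event), logical(1))
  list(km_present = km_estimate(time[present], event[present]),
       km_absent = km_estimate(time[!present], event[!present]),
       logrank = logrank_test(time, event, present),
       present = present)
}
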