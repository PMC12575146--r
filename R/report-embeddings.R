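#' Default stopword list for report preprocessing
#'
#' Short functional French words (articles, prepositions, common
#' adverbs); the exact list is a package choice and fully configurable.
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("le", "la", "les", "un", "une", "des", "de", "du", "au", "aux", "en",
    "et", "ou", "a", "d", "l", "ce", "cette", "ces", "son", "sa", "ses",
    "pour", "par", "sur", "dans", "avec", "est", "sont", "pas", "ne",
    "tres", "plus", "moins", "bien", "donc", "chez", "qui", "que")
}

#' Preprocess a free-text report into tokens
#'
#' Lowercases, strips accents and punctuation, splits on whitespace and
#' removes stopwords. Medical abbreviations pass through unexpanded. The
#' transformation is idempotent: preprocessing the rejoined output
#' reproduces it.
#'
#' @param text Report text (possibly empty or `NA`).
#' @param stopwords Character vector of tokens to drop.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' preprocess_report("Sein en involution adipeuse.")
#' @export
preprocess_report <- function(text, stopwords = default_stopwords()) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(trimws(gsub("\\s+", " ", strip_text(text))), " ")[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% stopwords]
}

#' Deterministic hash-based token embedder
#'
#' Maps any token string to a reproducible pseudo-random unit vector of
#' dimension `dim`, by seeding R's RNG with a polynomial rolling hash of
#' the token. The same token always yields the same vector on every
#' platform, which makes the whole text pathway bit-reproducible; the
#' default dimension 768 matches the reference contextual-embedding
#' plug-in so all dimension plumbing is identical. A cache avoids
#' re-hashing repeated tokens. Any other embedder (e.g. an adapter around
#' a pretrained French clinical language model) can be substituted as
#' long as it satisfies the same contract: deterministic
#' `embed(token) -> numeric(dim)`.
#'
#' @param dim Embedding dimension (default 768).
#' @param seed Salt mixed into the token hash.
#' @return An object of class `token_embedder` with elements `embed`
#'   (function) and `dim`.
#' @export
hash_embedder <- function(dim = 768, seed = 0L) {
  cache <- new.env(parent = emptyenv())
  hash_token <- function(token) {
    h <- 17
    for (code in utf8ToInt(token)) {
      h <- (h * 31 + code) %% 2147483563
    }
    as.integer((h + seed) %% 2147483563)
  }
  embed <- function(token) {
    if (!is.null(cache[[token]])) return(cache[[token]])
    v <- with_seed(hash_token(token), stats::rnorm(dim))
    v <- v / sqrt(sum(v * v))
    cache[[token]] <- v
    v
  }
  structure(list(embed = embed, dim = dim), class = "token_embedder")
}

#' Pool token vectors into a report vector
#'
#' Elementwise sum of all token embeddings of the report; an empty report
#' pools to the zero vector. Summation makes pooling linear and order
#' invariant.
#'
#' @param vectors List of equal-length numeric vectors (possibly empty).
#' @param dim Dimension used for the zero vector when `vectors` is empty.
#' @return Numeric vector.
#' @export
pool_report <- function(vectors, dim = NULL) {
  if (length(vectors) == 0L) {
    if (is.null(dim)) stop_input("empty report needs an explicit dimension")
    return(numeric(dim))
  }
  dims <- lengths(vectors)
  if (length(unique(dims)) != 1L) {
    stop_input("token vectors have inconsistent dimensions")
  }
  Reduce(`+`, vectors)
}

#' Embed one report
#' @param text Report text.
#' @param embedder A [hash_embedder()]-style embedder.
#' @param stopwords Stopword list for [preprocess_report()].
#' @return Numeric vector of dimension `embedder$dim`.
#' @export
embed_report <- function(text, embedder, stopwords = default_stopwords()) {
  toks <- preprocess_report(text, stopwords)
  pool_report(lapply(toks, embedder$embed), dim = embedder$dim)
}

#' Build the text trajectory of one patient
#'
#' Collects the reports dated from the diagnosis up to the index date
#' (surgery + 365 days), sorts them chronologically (stable for same-day
#' ties), pools each into a fixed-dimension vector, and assigns each
#' report the delay bucket of its gap to the previous report (first
#' report: `W0`).
#'
#' @param record A [patient_record()] with report texts on its visits.
#' @param embedder A token embedder (see [hash_embedder()]).
#' @param post_surgery_days Index-date offset (default 365).
#' @param stopwords Stopword list.
#' @return An object of class `report_trajectory`: `vectors` (n x dim
#'   matrix), `delays` (bucket labels), `dates`, and the `label` if
#'   present.
#' @export
build_text_trajectory <- function(record, embedder, post_surgery_days = 365,
                                  stopwords = default_stopwords()) {
  lo <- record$diagnosis_date
  hi <- record$surgery_date + post_surgery_days
  visits <- Filter(function(v) {
    !is.null(v$report_text) && !is.na(v$report_text) &&
      v$date >= lo && v$date <= hi
  }, record$visits)
  if (length(visits) == 0L) {
    stop_input("patient %s has no reports between diagnosis and index date",
               record$patient_id)
  }
  ord <- order(vapply(visits, function(v) as.numeric(v$date), numeric(1)))
  visits <- visits[ord]  # order() is stable: same-day reports keep file order
  vectors <- t(vapply(visits, function(v) {
    embed_report(v$report_text, embedder, stopwords)
  }, numeric(embedder$dim)))
  dates <- as.Date(vapply(visits, function(v) as.character(v$date),
                          character(1)))
  gaps <- c(0, as.numeric(diff(dates)))
  delays <- vapply(gaps, discretize_delay, character(1))
  structure(
    list(vectors = vectors, delays = delays, dates = dates,
         label = record$label %||% NA, patient_id = record$patient_id,
         dim = embedder$dim),
    class = "report_trajectory"
  )
}

#' @export
print.report_trajectory <- function(x, ...) {
  cat(sprintf("<report_trajectory %s: %d reports, dim %d, label %s>\n",
              x$patient_id %||% "?", nrow(x$vectors), x$dim,
              as.character(x$label)))
  invisible(x)
}
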