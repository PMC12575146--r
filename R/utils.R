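#' @keywords internal
"_PACKAGE"

# Rounding convention used for ages and biological deltas: half away from
# zero (round(0.5) = 1, round(-0.5) = -1), centralized here because base R's
# round() is banker's rounding.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers never perturb outer simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of distinct 31-bit seeds from one user seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}
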