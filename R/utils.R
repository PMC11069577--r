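# Shared internal helpers.

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive numbers (the convention used for all reported percentages).
#' Base `round()` rounds half to even, which would mis-report e.g. 22.75
#' as 22.7.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
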