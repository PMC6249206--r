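#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for
#' every displayed ratio in the package's reports. Base `round()` rounds
#' half to even, which differs at exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with display rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to the requested
#' number of decimal places.
#'
#' @param numerator count or real value.
#' @param denominator positive count.
#' @param decimals decimal places kept in the display value.
#' @return rounded percentage (numeric).
#' @export
percent <- function(numerator, denominator, decimals = 2) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("percent(): denominator must be positive")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

# Derive a reproducible sub-stream seed from a global seed and a stage label.
# Keeps results stable when stages are re-run in isolation.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
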