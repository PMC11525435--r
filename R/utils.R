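# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is given, otherwise use the
# current RNG stream. All user-facing stochastic functions funnel through this
# so that identical (inputs, seed) pairs are byte-identical.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

#' Format seconds as milliseconds
#'
#' Reports in this package always print milliseconds while every computation
#' is carried out in seconds; this is the single conversion point.
#'
#' @param x Time in seconds.
#' @param digits Number of decimal places in milliseconds.
#' @return Character vector like `"16.3 ms"`.
#' @export
#' @examples
#' format_ms(0.0163)
format_ms <- function(x, digits = 1) {
  paste0(formatC(x * 1000, format = "f", digits = digits), " ms")
}

# Sample standard deviation with the n-1 denominator; n = 1 yields 0 by
# convention (flagged upstream as low-n rather than NA).
sd_or_zero <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
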