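#' Round half up to integer
#'
#' Rounds to the nearest integer with ties going away from zero for positive
#' input, matching the convention used when percentages are printed in
#' figure captions (e.g. 65.5 -> 66). Base `round()` uses banker's rounding
#' and is unsuitable for reproducing printed integer percentages.
#'
#' @param x numeric vector (non-negative in all package uses)
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Integer percentage with round-half-up
#'
#' @param num numerator (count)
#' @param den denominator (total); `NA` is returned where `den == 0`
#' @return integer percentages; NA flags an undefined proportion
#' @export
pct_half_up <- function(num, den) {
  out <- rep(NA_real_, length(num))
  ok <- den > 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok])
  out
}

# internal: stop with a consistent message prefix
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
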