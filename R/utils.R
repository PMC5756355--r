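#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when converting attributable
#' fractions into integer counts of deaths and cases. Differs from base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded to `digits` places, ties going away from zero.
#' @examples
#' round_half_up(0.5)   # 1, not 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by one ulp so values like 2.345 stored as 2.34499... still go up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Deterministic 31-bit seed for a (seed, label) sub-stream. Keeps each
# factor/stratum on its own reproducible stream so adding a factor does not
# perturb the draws of the others.
stream_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}
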