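#' Log-linear slope per gram from a per-100 g/day relative risk
#'
#' Dose-response meta-analyses commonly report the RR per 100 g/day of intake.
#' Under a log-linear model the corresponding slope per gram per day is
#' \eqn{\beta = \ln(RR_{100}) / 100}: negative for protective exposures
#' (RR below 1), positive for harmful ones.
#'
#' @param rr_per_100g Relative risk per 100 g/day increase, > 0.
#' @return Log-RR per g/day.
#' @examples
#' log_slope_per_gram(1.14)  # red/processed meat, ~0.00131
#' log_slope_per_gram(0.94)  # fruit, ~-0.00062
#' @export
log_slope_per_gram <- function(rr_per_100g) {
  if (any(rr_per_100g <= 0))
    stop("`rr_per_100g` must be positive", call. = FALSE)
  log(rr_per_100g) / 100
}

#' Quantile-specific relative risks from a dose-response slope
#'
#' Represents each quantile by the lower bound of its intake range (the first
#' quantile's bound is 0), evaluates the log-linear risk at those bounds, and
#' rescales so the designated reference quantile — the top quantile for a
#' protective exposure, the bottom for a harmful one — has RR exactly 1:
#' \deqn{RR_i = \exp\{\beta (L_i - L_{ref})\}.}
#'
#' @param beta Log-RR per g/day, e.g. from [log_slope_per_gram()].
#' @param lower_bounds Strictly increasing quantile lower bounds in g/day;
#'   first entry 0.
#' @param reference_index Index of the reference quantile.
#' @param digits Optional rounding of the result for display (e.g. 2); `NULL`
#'   (default) returns full precision.
#' @return Vector of relative risks, reference entry exactly 1.
#' @examples
#' # red/processed meat, urban men: top quintile RR ~1.27
#' quantile_rrs_from_slope(log(1.14) / 100, c(0, 50, 83.3, 120, 183.3),
#'                         reference_index = 1, digits = 2)
#' @export
quantile_rrs_from_slope <- function(beta, lower_bounds, reference_index,
                                    digits = NULL) {
  check_bounds(lower_bounds, reference_index)
  rr <- exp(beta * (lower_bounds - lower_bounds[reference_index]))
  rr[reference_index] <- 1  # exact, immune to floating-point drift
  if (!is.null(digits)) rr <- round_half_up(rr, digits)
  rr
}

#' Fit a dose-response slope from quantile-specific relative risks
#'
#' Inverse of [quantile_rrs_from_slope()]: least-squares fit of
#' \eqn{\ln RR_i} against \eqn{L_i - L_{ref}} through the origin,
#' \eqn{\hat\beta = \sum x_i \ln RR_i / \sum x_i^2}. With a single
#' non-reference level this is exact inversion. Used to reconstruct the
#' per-100 g/day slope behind a published quantile RR table.
#'
#' @param lower_bounds Quantile lower bounds in g/day.
#' @param rrs Relative risks per quantile (reference entry 1).
#' @param reference_index Index of the reference quantile.
#' @return Log-RR per g/day. Multiply by 100 and exponentiate for the
#'   per-100 g/day RR.
#' @examples
#' b <- fit_slope_from_levels(c(0, 50, 83.3, 120, 183.3),
#'                            c(1, 1.07, 1.12, 1.17, 1.27), 1)
#' exp(100 * b)  # ~1.14 per 100 g/day
#' @export
fit_slope_from_levels <- function(lower_bounds, rrs, reference_index) {
  check_bounds(lower_bounds, reference_index)
  stopifnot(length(rrs) == length(lower_bounds))
  if (any(rrs <= 0)) stop("relative risks must be positive", call. = FALSE)
  x <- (lower_bounds - lower_bounds[reference_index])[-reference_index]
  y <- log(rrs[-reference_index])
  if (length(x) == 0 || all(y == 0) && all(x == 0))
    stop("slope undefined: no non-reference information", call. = FALSE)
  sum(x * y) / sum(x^2)
}

check_bounds <- function(lower_bounds, reference_index) {
  if (length(lower_bounds) < 2)
    stop("need at least two quantile bounds", call. = FALSE)
  if (lower_bounds[1] != 0)
    stop("first quantile lower bound must be 0", call. = FALSE)
  if (any(diff(lower_bounds) <= 0))
    stop("quantile lower bounds must be strictly increasing", call. = FALSE)
  if (reference_index < 1 || reference_index > length(lower_bounds))
    stop("`reference_index` out of range", call. = FALSE)
  invisible(TRUE)
}
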