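#' Standard deviation of a log relative risk from its confidence interval
#'
#' Assuming the CI is symmetric on the log scale (the usual construction for
#' ratio measures), \eqn{\sigma_{\ln RR} = (\ln hi - \ln lo) / (2z)}.
#'
#' @param rr_ci Length-2 vector `(low, high)`, both > 0.
#' @param z Normal quantile the interval was built with (default 1.96).
#' @return Standard deviation of the log RR.
#' @examples
#' rr_log_sd(c(1.09, 1.24))  # smoking RR 1.16 -> ~0.0329
#' @export
rr_log_sd <- function(rr_ci, z = 1.96) {
  if (length(rr_ci) != 2 || any(rr_ci <= 0))
    stop("`rr_ci` must be two positive bounds", call. = FALSE)
  if (rr_ci[1] > rr_ci[2]) stop("CI bounds out of order", call. = FALSE)
  (log(rr_ci[2]) - log(rr_ci[1])) / (2 * z)
}

#' Delta-method confidence interval for a binary-exposure PAF
#'
#' First-order propagation of RR (and optionally prevalence) uncertainty
#' through Levin's formula. With \eqn{D = 1 + p(rr - 1)},
#' \deqn{\partial PAF/\partial rr = p / D^2, \quad
#'       \partial PAF/\partial p = (rr - 1) / D^2,}
#' and \eqn{var(PAF) \approx (p/D^2)^2 (rr\,\sigma_{\ln RR})^2 +
#' ((rr-1)/D^2)^2 \sigma_p^2}, where \eqn{rr\,\sigma_{\ln RR}} is the
#' delta-method SD of the RR itself under lognormal sampling. The interval
#' \eqn{PAF \pm z\,sd} is truncated to \[0, 1).
#'
#' @param p Exposure prevalence.
#' @param rr Relative risk.
#' @param rr_ci Length-2 CI for the RR.
#' @param p_sd Standard deviation of the prevalence estimate (default 0: the
#'   interval is RR-driven).
#' @param z Normal quantile for the output interval (default 1.96 for 95%).
#' @param rr_ci_z Normal quantile the RR confidence interval was built with
#'   (default 1.96), used to recover \eqn{\sigma_{\ln RR}}.
#' @return Length-2 vector `(low, high)`.
#' @examples
#' paf_ci_delta(0.574, 1.16, c(1.09, 1.24))
#' @export
paf_ci_delta <- function(p, rr, rr_ci, p_sd = 0, z = 1.96, rr_ci_z = 1.96) {
  paf <- levin_paf(p, rr)
  s_log <- rr_log_sd(rr_ci, rr_ci_z)
  d2 <- (1 + p * (rr - 1))^2
  v <- (p / d2)^2 * (rr * s_log)^2 + ((rr - 1) / d2)^2 * p_sd^2
  truncate_ci(paf + c(-1, 1) * z * sqrt(v))
}

#' Monte-Carlo confidence interval for a (multi-level) PAF
#'
#' Draws \eqn{\ln RR_i \sim N(\ln rr_i, \sigma_i)} independently per level,
#' recomputes the multi-level PAF for each draw, and returns the percentile
#' interval matching `z`. Deterministic for a fixed seed. Non-finite draws
#' (possible only with degenerate inputs) are dropped with a warning.
#'
#' @param p Level prevalences (non-reference levels).
#' @param rr Level relative risks.
#' @param sd_log Per-level SDs of the log RRs, e.g. from [rr_log_sd()].
#' @param draws Number of Monte-Carlo draws (>= 1000 recommended).
#' @param seed Integer seed.
#' @param z Normal quantile defining the coverage (1.96 -> 95%).
#' @return Length-2 vector `(low, high)`.
#' @examples
#' paf_ci_mc(0.574, 1.16, rr_log_sd(c(1.09, 1.24)), draws = 5000, seed = 1)
#' @export
paf_ci_mc <- function(p, rr, sd_log, draws = 10000L, seed = 1L, z = 1.96) {
  stopifnot(length(p) == length(rr), length(sd_log) %in% c(1L, length(rr)))
  sd_log <- rep_len(sd_log, length(rr))
  set.seed(seed)
  sims <- vapply(seq_len(draws), function(i) {
    rr_i <- exp(stats::rnorm(length(rr), log(rr), sd_log))
    multi_level_paf(p, rr_i)
  }, numeric(1))
  bad <- !is.finite(sims)
  if (any(bad)) {
    warning(sum(bad), " non-finite draws excluded")
    sims <- sims[!bad]
  }
  alpha <- 2 * stats::pnorm(-z)
  truncate_ci(unname(stats::quantile(sims, c(alpha / 2, 1 - alpha / 2))))
}

truncate_ci <- function(ci) pmin(pmax(ci, 0), 1 - 1e-12)

# Delta-method variance for a multi-level PAF: first-order in each level RR,
# var = sum_i (p_i / D^2)^2 (rr_i sigma_i)^2 with D = 1 + sum p_i (rr_i - 1).
multi_level_paf_var <- function(p, rr, sd_log) {
  d2 <- (1 + sum(p * (rr - 1)))^2
  sum(((p / d2) * rr * sd_log)^2)
}

# CI for one factor-sex cell, matching factor_sex_paf's pooling. Regions are
# treated as independent for the delta route; the MC route redraws jointly.
factor_sex_ci <- function(levels, urban_weight, method, z, draws, seed) {
  non_ref <- levels[!levels$is_reference, , drop = FALSE]
  sd_log <- mapply(function(lo, hi) rr_log_sd(c(lo, hi), z),
                   non_ref$rr_lo, non_ref$rr_hi)
  regions <- unique(levels$region)
  if (method == "delta") {
    if (identical(regions, "national")) {
      v <- multi_level_paf_var(non_ref$prevalence, non_ref$rr, sd_log)
      paf <- multi_level_paf(non_ref$prevalence, non_ref$rr)
    } else {
      u <- non_ref$region == "urban"
      vu <- multi_level_paf_var(non_ref$prevalence[u], non_ref$rr[u], sd_log[u])
      vr <- multi_level_paf_var(non_ref$prevalence[!u], non_ref$rr[!u], sd_log[!u])
      v <- urban_weight^2 * vu + (1 - urban_weight)^2 * vr
      paf <- pool_regions(
        multi_level_paf(non_ref$prevalence[u], non_ref$rr[u]),
        multi_level_paf(non_ref$prevalence[!u], non_ref$rr[!u]), urban_weight)
    }
    return(truncate_ci(paf + c(-1, 1) * z * sqrt(v)))
  }
  set.seed(seed)
  sims <- vapply(seq_len(draws), function(i) {
    rr_i <- exp(stats::rnorm(nrow(non_ref), log(non_ref$rr), sd_log))
    df <- non_ref
    df$rr <- pmax(rr_i, 1)  # exposure coding keeps harmful levels at RR >= 1
    df$is_reference <- FALSE
    factor_sex_paf(df, urban_weight)
  }, numeric(1))
  alpha <- 2 * stats::pnorm(-z)
  truncate_ci(unname(stats::quantile(sims, c(alpha / 2, 1 - alpha / 2))))
}

# Death-weighted combination of the two per-sex CIs (independence assumed).
pooled_total_ci <- function(per_sex, burden, z) {
  d <- burden$deaths[match(c("male", "female"), burden$sex)]
  wts <- d / sum(d)
  half <- vapply(per_sex, function(e) (e$ci_high - e$ci_low) / 2, numeric(1))
  paf <- sum(wts * vapply(per_sex, function(e) e$paf, numeric(1)))
  truncate_ci(paf + c(-1, 1) * sqrt(sum((wts * half)^2)))
}

# MC interval for the combined (multi-factor) PAF of one stratum. RRs are
# drawn independently across factors and levels; male and female share a draw
# where the configuration gives both sexes the same point RR and CI.
combined_ci_mc <- function(config, urban_weight, stratum, z, draws, seed) {
  set.seed(seed)
  burden <- config$burden
  d <- burden$deaths[match(c("male", "female"), burden$sex)]
  sims <- vapply(seq_len(draws), function(i) {
    per_factor <- vapply(config$factor_names, function(fct) {
      pafs <- vapply(c("male", "female"), function(sx) {
        lv <- config$exposure[config$exposure$factor == fct &
                                config$exposure$sex == sx, , drop = FALSE]
        nr <- lv[!lv$is_reference, , drop = FALSE]
        sd_log <- mapply(function(lo, hi) rr_log_sd(c(lo, hi), z),
                         nr$rr_lo, nr$rr_hi)
        nr$rr <- pmax(exp(stats::rnorm(nrow(nr), log(nr$rr), sd_log)), 1)
        nr$is_reference <- FALSE
        factor_sex_paf(nr, urban_weight)
      }, numeric(1))
      switch(stratum,
             male = pafs[["male"]], female = pafs[["female"]],
             total = sum(d * pafs) / sum(d))
    }, numeric(1))
    combine_pafs(per_factor)
  }, numeric(1))
  alpha <- 2 * stats::pnorm(-z)
  truncate_ci(unname(stats::quantile(sims, c(alpha / 2, 1 - alpha / 2))))
}
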