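#' Levin's population attributable fraction for a binary exposure
#'
#' For an exposure with population prevalence \eqn{P} and relative risk
#' \eqn{RR}, the fraction of cases attributable to the exposure is
#' \deqn{PAF = \frac{P (RR - 1)}{P (RR - 1) + 1}.}
#' Negative values (when \eqn{RR < 1}) are mathematically valid and returned;
#' the result is always strictly below 1.
#'
#' @param p Exposure prevalence, a proportion in \[0, 1\]. Vectorised.
#' @param rr Relative risk, > 0. Vectorised.
#' @return The attributable fraction, strictly < 1.
#' @examples
#' levin_paf(0.574, 1.16)  # ~0.084: smoking among Chinese men
#' levin_paf(0.3, 1)       # null effect -> 0
#' @seealso [multi_level_paf()] for categorised exposures.
#' @export
levin_paf <- function(p, rr) {
  stopifnot(is.numeric(p), is.numeric(rr))
  if (any(p < 0 | p > 1)) stop("prevalence `p` must lie in [0, 1]", call. = FALSE)
  if (any(rr <= 0)) stop("relative risk `rr` must be positive", call. = FALSE)
  excess <- p * (rr - 1)
  excess / (excess + 1)
}

#' Multi-level population attributable fraction ("full shift")
#'
#' Attributable fraction for an exposure categorised into levels, under the
#' counterfactual that the whole population moves to the reference level:
#' \deqn{PAF = \frac{\sum_i P_i (RR_i - 1)}{\sum_i P_i (RR_i - 1) + 1}.}
#' Reference levels carry \eqn{RR = 1} and contribute nothing, so they may be
#' omitted. With a single non-reference level this reduces exactly to
#' [levin_paf()].
#'
#' @param p Vector of level prevalences, each >= 0, summing to <= 1.
#' @param rr Vector of level relative risks (> 0), same length as `p`.
#' @return The attributable fraction, strictly < 1.
#' @examples
#' # overweight + obesity among women
#' multi_level_paf(c(0.1697, 0.0341), c(1.25, 1.57))  # ~0.058
#' # quintile exposure, 20% prevalence per quintile
#' multi_level_paf(rep(0.2, 4), c(1.46, 1.27, 1.18, 1.10))  # ~0.168
#' @export
multi_level_paf <- function(p, rr) {
  stopifnot(is.numeric(p), is.numeric(rr), length(p) == length(rr))
  if (any(p < 0)) stop("level prevalences must be non-negative", call. = FALSE)
  if (sum(p) > 1 + 1e-9) stop("level prevalences sum to more than 1", call. = FALSE)
  if (any(rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  excess <- sum(p * (rr - 1))
  excess / (excess + 1)
}

#' Combine attributable fractions across independent risk factors
#'
#' Joint PAF for several factors assumed to act multiplicatively and
#' independently:
#' \deqn{PAF = 1 - \prod_k (1 - PAF_k).}
#' Order-invariant; never exceeds the sum of the inputs (for non-negative
#' inputs) and never falls below their maximum.
#'
#' @param pafs Numeric vector of attributable fractions, each < 1.
#' @return Combined attributable fraction, < 1.
#' @examples
#' combine_pafs(c(0.5, 0.5))  # 0.75
#' @export
combine_pafs <- function(pafs) {
  stopifnot(is.numeric(pafs), length(pafs) >= 1)
  if (any(pafs >= 1)) stop("every PAF must be below 1", call. = FALSE)
  1 - prod(1 - pafs)
}

#' Pool urban and rural attributable fractions
#'
#' Weighted arithmetic mean of two stratum PAFs. Used to collapse
#' region-specific dietary PAFs into one per-sex estimate.
#'
#' @param urban_paf,rural_paf Stratum attributable fractions.
#' @param urban_weight Weight on the urban stratum, in \[0, 1\]; the rural
#'   stratum receives the complement.
#' @return Pooled attributable fraction.
#' @examples
#' pool_regions(0.0584, 0.0637, 1/3)  # ~0.062
#' @export
pool_regions <- function(urban_paf, rural_paf, urban_weight) {
  if (urban_weight < 0 || urban_weight > 1)
    stop("`urban_weight` must lie in [0, 1]", call. = FALSE)
  urban_weight * urban_paf + (1 - urban_weight) * rural_paf
}

#' Convert an attributable fraction into an attributable count
#'
#' Multiplies a PAF by a stratum's total deaths or incident cases. The
#' `"round3"` policy first rounds the PAF to three decimals (one decimal in
#' percent) and then multiplies — the display-precision convention under which
#' published burden tables are internally consistent (e.g. 79,000 x 0.084 =
#' 6,636). `"exact"` multiplies at full precision. The product is rounded
#' half-up to an integer either way.
#'
#' @param paf Attributable fraction, < 1.
#' @param counts Total deaths or cases in the stratum (non-negative).
#' @param policy `"round3"` (default) or `"exact"`.
#' @return Integer attributable count.
#' @examples
#' attributable_counts(0.08411, 79000)                   # 6636
#' attributable_counts(0.08411, 79000, policy = "exact") # 6645
#' @export
attributable_counts <- function(paf, counts, policy = c("round3", "exact")) {
  policy <- match.arg(policy)
  if (any(paf >= 1)) stop("PAF must be below 1", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (policy == "round3") paf <- round_half_up(paf, 3)
  as.integer(round_half_up(paf * counts))
}

#' Pool sex-specific attributable-burden estimates
#'
#' Total attributable deaths and cases are the sums over sexes; the pooled PAF
#' is total attributable deaths divided by total deaths, so it always lies
#' between the per-sex PAFs.
#'
#' @param male,female One-row data frames (or lists) with fields `factor`,
#'   `paf`, `attributable_deaths`, `attributable_cases`.
#' @param burden Data frame with columns `sex`, `deaths`, `incidence`.
#' @return A [tibble::tibble()] row for the pooled stratum.
#' @export
pool_sexes <- function(male, female, burden) {
  if (!identical(male$factor, female$factor))
    stop("cannot pool estimates for different factors: ",
         male$factor, " vs ", female$factor, call. = FALSE)
  total_deaths <- sum(burden$deaths)
  deaths <- male$attributable_deaths + female$attributable_deaths
  cases <- male$attributable_cases + female$attributable_cases
  tibble::tibble(
    factor = male$factor, stratum = "total",
    paf = deaths / total_deaths,
    attributable_deaths = as.integer(deaths),
    attributable_cases = as.integer(cases)
  )
}

# Per-sex PAF for one factor: multi-level PAF per region, then region pooling
# when the factor is region-stratified. `levels` is the factor's exposure
# table restricted to one sex.
factor_sex_paf <- function(levels, urban_weight) {
  non_ref <- levels[!levels$is_reference, , drop = FALSE]
  if (any(non_ref$rr < 1))
    stop("factor '", non_ref$factor[1], "' has a non-reference RR below 1; ",
         "code exposures so that the harmful level carries RR >= 1",
         call. = FALSE)
  regions <- unique(levels$region)
  if (identical(regions, "national")) {
    return(multi_level_paf(non_ref$prevalence, non_ref$rr))
  }
  if (!setequal(regions, c("urban", "rural")))
    stop("regions must be 'national' or the pair 'urban'/'rural'", call. = FALSE)
  u <- non_ref[non_ref$region == "urban", ]
  r <- non_ref[non_ref$region == "rural", ]
  pool_regions(multi_level_paf(u$prevalence, u$rr),
               multi_level_paf(r$prevalence, r$rr),
               urban_weight)
}

#' Run the full attributable-burden analysis
#'
#' Orchestrates the whole pipeline over a study configuration: per-factor
#' per-sex PAFs (region-pooled for urban/rural-stratified factors), sex
#' pooling via attributable-death totals, the multiplicative combined PAF per
#' sex and overall, and attributable deaths/cases throughout. Combined
#' attributable counts are sums of the sex-specific combined counts; the
#' combined total PAF is computed multiplicatively from the factor-level total
#' PAFs, so the two may disagree slightly — both are reported as is.
#'
#' Confidence intervals use the delta method (`ci = "delta"`) or Monte-Carlo
#' propagation of lognormal RR draws (`ci = "mc"`); `ci = "none"` skips them.
#'
#' @param config A `study_config`, e.g. from [read_study_config()] or
#'   [china_crc_2012()].
#' @param urban_weight Override for the config's urban pooling weight.
#' @param ci One of `"none"`, `"delta"`, `"mc"`.
#' @param draws Monte-Carlo draws per interval (when `ci = "mc"`).
#' @param seed Seed for Monte-Carlo draws.
#' @param policy Count rounding policy, see [attributable_counts()].
#' @return A tibble with columns `factor`, `stratum` (`male`, `female`,
#'   `total`), `paf`, `ci_low`, `ci_high`, `attributable_deaths`,
#'   `attributable_cases`; one row per factor and stratum plus three
#'   `combined` rows.
#' @examples
#' res <- run_study(china_crc_2012())
#' subset(res, factor == "tobacco_smoking" & stratum == "male")
#' @export
run_study <- function(config, urban_weight = NULL, ci = c("none", "delta", "mc"),
                      draws = 10000L, seed = 1L, policy = "round3") {
  ci <- match.arg(ci)
  stopifnot(inherits(config, "study_config"))
  w <- if (is.null(urban_weight)) config$pooling$urban_weight else urban_weight
  burden <- config$burden
  z <- config$z %||% 1.96

  rows <- list()
  for (fct in config$factor_names) {
    per_sex <- list()
    for (sx in c("male", "female")) {
      lv <- config$exposure[config$exposure$factor == fct &
                              config$exposure$sex == sx, , drop = FALSE]
      paf <- factor_sex_paf(lv, w)
      interval <- c(NA_real_, NA_real_)
      if (ci != "none") {
        interval <- factor_sex_ci(lv, w, method = ci, z = z, draws = draws,
                                  seed = stream_seed(seed, fct, sx))
      }
      b <- burden[burden$sex == sx, ]
      per_sex[[sx]] <- tibble::tibble(
        factor = fct, stratum = sx, paf = paf,
        ci_low = interval[1], ci_high = interval[2],
        attributable_deaths = attributable_counts(paf, b$deaths, policy),
        attributable_cases = attributable_counts(paf, b$incidence, policy)
      )
    }
    tot <- pool_sexes(per_sex$male, per_sex$female, burden)
    tot$ci_low <- NA_real_
    tot$ci_high <- NA_real_
    if (ci != "none") {
      iv <- pooled_total_ci(per_sex, burden, z)
      tot$ci_low <- iv[1]; tot$ci_high <- iv[2]
    }
    rows <- c(rows, per_sex, list(tot[, names(per_sex$male)]))
  }
  res <- dplyr::bind_rows(rows)

  disp <- function(x) round_half_up(x, 3)  # combine at display precision
  combined <- list()
  for (sx in c("male", "female")) {
    sub <- res[res$stratum == sx, ]
    cpaf <- combine_pafs(disp(sub$paf))
    b <- burden[burden$sex == sx, ]
    combined[[sx]] <- tibble::tibble(
      factor = "combined", stratum = sx, paf = cpaf,
      ci_low = NA_real_, ci_high = NA_real_,
      attributable_deaths = attributable_counts(cpaf, b$deaths, policy),
      attributable_cases = attributable_counts(cpaf, b$incidence, policy)
    )
  }
  tot_paf <- combine_pafs(disp(res$paf[res$stratum == "total"]))
  combined$total <- tibble::tibble(
    factor = "combined", stratum = "total", paf = tot_paf,
    ci_low = NA_real_, ci_high = NA_real_,
    attributable_deaths = combined$male$attributable_deaths +
      combined$female$attributable_deaths,
    attributable_cases = combined$male$attributable_cases +
      combined$female$attributable_cases
  )
  if (ci == "mc") {
    for (sx in c("male", "female", "total")) {
      iv <- combined_ci_mc(config, w, stratum = sx, z = z, draws = draws,
                           seed = stream_seed(seed, "combined", sx))
      combined[[sx]]$ci_low <- iv[1]; combined[[sx]]$ci_high <- iv[2]
    }
  }
  dplyr::bind_rows(res, dplyr::bind_rows(combined))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
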