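#' Configure a synthetic attributable-burden study
#'
#' Wraps a `study_config` whose prevalences and RRs are taken as ground truth,
#' together with the simulation sizes: `survey_n` individuals per
#' factor-stratum cross-sectional exposure survey (Bernoulli for binary
#' factors, multinomial for leveled ones), a baseline disease risk `r0`, and a
#' finite population of `population_n` individuals for the counterfactual
#' oracle. Every draw is keyed to `(seed, factor, sex, region)` so adding a
#' factor never perturbs another factor's stream.
#'
#' @param study A `study_config` holding the generating parameters.
#' @param survey_n Survey size per stratum (>= 1).
#' @param r0 Baseline risk in (0, 1) for the population oracle.
#' @param population_n Simulated population size per stratum.
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(study, survey_n = 50000L, r0 = 0.01,
                             population_n = 1000000L, seed) {
  stopifnot(inherits(study, "study_config"), survey_n >= 1,
            r0 > 0, r0 < 1, population_n >= 1)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(study = study, survey_n = as.integer(survey_n), r0 = r0,
                 population_n = as.integer(population_n),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Ground-truth PAF of a synthetic factor
#'
#' Closed-form attributable fraction from the generating prevalences and RRs
#' (region-pooled for urban/rural factors) — the recovery target for the
#' simulation pipeline.
#'
#' @param sc A `synthetic_config`.
#' @param factor Factor name.
#' @param sex `"male"` or `"female"`.
#' @return The true attributable fraction.
#' @export
true_paf <- function(sc, factor, sex = "male") {
  stopifnot(inherits(sc, "synthetic_config"))
  ex <- sc$study$exposure
  lv <- ex[ex$factor == factor & ex$sex == sex, , drop = FALSE]
  if (nrow(lv) == 0) stop("unknown factor/sex: ", factor, "/", sex, call. = FALSE)
  factor_sex_paf(lv, sc$study$pooling$urban_weight %||% 1/3)
}

#' Simulate a cross-sectional exposure survey
#'
#' Draws `survey_n` individuals' exposure levels from the true level
#' prevalences of one factor-stratum (multinomial; Bernoulli in the binary
#' case) and returns the estimated prevalences. Reproducible: the stream is
#' keyed to `(seed, factor, sex, region)`.
#'
#' @param sc A `synthetic_config`.
#' @param factor Factor name.
#' @param sex,region Stratum selectors.
#' @return Tibble with columns `level`, `n`, `prevalence` (estimated),
#'   `true_prevalence`.
#' @export
generate_survey <- function(sc, factor, sex = "male", region = "national") {
  stopifnot(inherits(sc, "synthetic_config"))
  ex <- sc$study$exposure
  lv <- ex[ex$factor == factor & ex$sex == sex & ex$region == region, ,
           drop = FALSE]
  if (nrow(lv) == 0)
    stop("unknown stratum: ", factor, "/", sex, "/", region, call. = FALSE)
  set.seed(stream_seed(sc$seed, "survey", factor, sex, region))
  counts <- as.vector(stats::rmultinom(1, sc$survey_n, lv$prevalence))
  tibble::tibble(level = lv$level, n = counts,
                 prevalence = counts / sc$survey_n,
                 true_prevalence = lv$prevalence)
}

#' Build an estimated study configuration from simulated surveys
#'
#' Replaces every stratum's true prevalences with survey estimates from
#' [generate_survey()], keeping RRs fixed (surveys inform exposure only, as in
#' the real design). The result is a valid `study_config` ready for
#' [run_study()].
#'
#' @param sc A `synthetic_config`.
#' @return A `study_config` with estimated prevalences.
#' @export
synthetic_study <- function(sc) {
  study <- sc$study
  ex <- study$exposure
  for (fct in unique(ex$factor)) {
    for (sx in unique(ex$sex[ex$factor == fct])) {
      sel0 <- ex$factor == fct & ex$sex == sx
      for (rg in unique(ex$region[sel0])) {
        sel <- which(sel0 & ex$region == rg)
        svy <- generate_survey(sc, fct, sx, rg)
        ex$prevalence[sel] <- svy$prevalence[match(ex$level[sel], svy$level)]
      }
    }
  }
  study$exposure <- ex
  validate_study_config(study)
  study
}

#' Finite-population counterfactual oracle for one factor-stratum
#'
#' Assigns each of `population_n` individuals an exposure level from the true
#' prevalences, gives level \eqn{i} case probability \eqn{r_0 RR_i}, and
#' compares the expected factual case count \eqn{r_0 \sum n_i RR_i} with the
#' counterfactual count \eqn{n r_0} in which everyone sits at the reference
#' level. The empirical PAF, \eqn{1 - E_{ref} / E_{obs}}, converges to the
#' closed-form attributable fraction; expected-value comparison (rather than
#' per-individual case matching) keeps the Monte-Carlo variance down to the
#' multinomial sampling of exposure. Realised case counts are also drawn for
#' completeness.
#'
#' @param sc A `synthetic_config`.
#' @param factor Factor name.
#' @param sex,region Stratum selectors.
#' @return List with `empirical_paf`, `expected_factual`,
#'   `expected_counterfactual`, `factual_cases`, `counterfactual_cases`,
#'   `exposure_counts`.
#' @export
generate_population_counts <- function(sc, factor, sex = "male",
                                       region = "national") {
  stopifnot(inherits(sc, "synthetic_config"))
  ex <- sc$study$exposure
  lv <- ex[ex$factor == factor & ex$sex == sex & ex$region == region, ,
           drop = FALSE]
  if (nrow(lv) == 0)
    stop("unknown stratum: ", factor, "/", sex, "/", region, call. = FALSE)
  if (sc$r0 * max(lv$rr) >= 1)
    stop("r0 * max(RR) must stay below 1", call. = FALSE)
  set.seed(stream_seed(sc$seed, "population", factor, sex, region))
  n <- sc$population_n
  counts <- as.vector(stats::rmultinom(1, n, lv$prevalence))
  e_obs <- sc$r0 * sum(counts * lv$rr)
  e_ref <- n * sc$r0
  factual <- sum(stats::rbinom(nrow(lv), counts, sc$r0 * lv$rr))
  counterfactual <- stats::rbinom(1, n, sc$r0)
  list(empirical_paf = 1 - e_ref / e_obs,
       expected_factual = e_obs, expected_counterfactual = e_ref,
       factual_cases = factual, counterfactual_cases = counterfactual,
       exposure_counts = stats::setNames(counts, lv$level))
}

#' End-to-end parameter recovery report
#'
#' Simulates surveys for every factor-stratum, runs the estimated study
#' through the PAF pipeline, and compares each per-sex PAF with its ground
#' truth. The tolerance is 3 standard errors of the estimated PAF under
#' multinomial survey sampling, propagated by the delta method:
#' \eqn{var(PAF) \approx var(\sum \hat p_i (RR_i - 1)) / (1 + S)^4}.
#'
#' @param sc A `synthetic_config`.
#' @return Tibble with columns `factor`, `sex`, `true_paf`, `estimated_paf`,
#'   `error`, `se`, `pass`; attribute `combined_ok` reports whether the
#'   combined PAF was also recovered.
#' @export
end_to_end_recovery <- function(sc) {
  est_study <- synthetic_study(sc)
  w <- est_study$pooling$urban_weight %||% 1/3
  ex_true <- sc$study$exposure
  rows <- list()
  for (fct in sc$study$factor_names) {
    for (sx in c("male", "female")) {
      lv_t <- ex_true[ex_true$factor == fct & ex_true$sex == sx, , drop = FALSE]
      lv_e <- est_study$exposure[est_study$exposure$factor == fct &
                                   est_study$exposure$sex == sx, , drop = FALSE]
      truth <- factor_sex_paf(lv_t, w)
      est <- factor_sex_paf(lv_e, w)
      v <- 0
      for (rg in unique(lv_t$region)) {
        sub <- lv_t[lv_t$region == rg, ]
        cc <- sub$rr - 1
        s <- sum(sub$prevalence * cc)
        var_s <- (sum(cc^2 * sub$prevalence) - s^2) / sc$survey_n
        wt <- if (rg == "national") 1 else if (rg == "urban") w else 1 - w
        v <- v + wt^2 * var_s / (1 + s)^4
      }
      se <- sqrt(v)
      rows[[paste(fct, sx)]] <- tibble::tibble(
        factor = fct, sex = sx, true_paf = truth, estimated_paf = est,
        error = est - truth, se = se, pass = abs(est - truth) < 3 * se)
    }
  }
  out <- dplyr::bind_rows(rows)
  true_comb <- combine_pafs(vapply(sc$study$factor_names, function(f)
    true_paf(sc, f, "male"), numeric(1)))
  est_comb <- combine_pafs(out$estimated_paf[out$sex == "male"])
  attr(out, "combined_true") <- true_comb
  attr(out, "combined_estimated") <- est_comb
  attr(out, "combined_ok") <- abs(est_comb - true_comb) < 3 * sqrt(sum(
    ((1 - est_comb) / (1 - out$estimated_paf[out$sex == "male"]))^2 *
      out$se[out$sex == "male"]^2))
  out
}
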