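# Shared fixtures, built in code.

fixture_config <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- china_crc_2012()
    cached
  }
})

# A small two-factor study (one binary, one quintile) with known parameters,
# used by validation and synthetic-recovery tests.
toy_config <- function(urban_weight = 1/3) {
  exposure <- tibble::tibble(
    factor = c(rep("smoke", 4), rep("meat", 10)),
    sex = c("male", "male", "female", "female",
            rep(c("male", "female"), each = 5)),
    region = c(rep("national", 4), rep("urban", 10)),
    level = c("yes", "no", "yes", "no", rep(paste0("Q", 1:5), 2)),
    prevalence = c(0.574, 0.426, 0.026, 0.974, rep(0.2, 10)),
    rr = c(1.16, 1, 1.16, 1, 1, 1.07, 1.12, 1.17, 1.27,
           1, 1.04, 1.09, 1.14, 1.22),
    rr_lo = c(1.09, 1, 1.09, 1, 1, 1.02, 1.03, 1.05, 1.07,
              1, 1.01, 1.03, 1.04, 1.06),
    rr_hi = c(1.24, 1, 1.24, 1, 1, 1.11, 1.20, 1.29, 1.48,
              1, 1.07, 1.15, 1.24, 1.38),
    is_reference = c(FALSE, TRUE, FALSE, TRUE,
                     TRUE, FALSE, FALSE, FALSE, FALSE,
                     TRUE, FALSE, FALSE, FALSE, FALSE),
    lower_bound = c(rep(NA, 4), rep(c(0, 50, 83.3, 120, 183.3), 2))
  )
  # make the meat stratum national-free: mirror urban rows as rural so the
  # region pair is complete
  rural <- exposure[exposure$region == "urban", ]
  rural$region <- "rural"
  exposure <- dplyr::bind_rows(exposure, rural)
  structure(list(
    name = "toy",
    factors = tibble::tibble(
      name = c("smoke", "meat"),
      kind = c("binary", "quantile_dose_response"),
      direction = c("harmful", "harmful")),
    factor_names = c("smoke", "meat"),
    exposure = exposure,
    burden = tibble::tibble(sex = c("male", "female"),
                            deaths = c(1000L, 800L),
                            incidence = c(2000L, 1500L)),
    pooling = list(urban_weight = urban_weight),
    z = 1.96, use_printed_rrs = TRUE, published_pafs = NULL
  ), class = "study_config")
}

# exposure rows for one factor/sex of the packaged study
fixture_levels <- function(cfg, fct, sx) {
  cfg$exposure[cfg$exposure$factor == fct & cfg$exposure$sex == sx, ]
}

# printed per-quintile RRs (non-reference, Q1 downwards) for a dietary
# factor/sex/region of the packaged study
fixture_rrs <- function(cfg, fct, sx, rg) {
  lv <- cfg$exposure[cfg$exposure$factor == fct & cfg$exposure$sex == sx &
                       cfg$exposure$region == rg, ]
  lv$rr[!lv$is_reference]
}
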