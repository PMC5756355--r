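test_that("Levin's formula reproduces the published binary-factor PAFs", {
  # smoking and physical inactivity among men, to published 1-dp display
  expect_equal(round_half_up(100 * levin_paf(0.574, 1.16), 1), 8.4)
  expect_equal(round_half_up(100 * levin_paf(0.304, 1.32), 1), 8.9)
  expect_equal(levin_paf(0.574, 1.16), 0.574 * 0.16 / (0.574 * 0.16 + 1))
  # null effect and input validation
  expect_equal(levin_paf(c(0, 0.3, 1), 1), c(0, 0, 0))
  expect_lt(levin_paf(1, 100), 1)
  expect_lt(levin_paf(0.5, 0.5), 0)  # protective coding allowed in the math
  expect_error(levin_paf(1.2, 1.1), "prevalence")
  expect_error(levin_paf(0.5, -1), "positive")
})

test_that("multi-level PAF handles leveled exposures and reduces to Levin", {
  # overweight + obesity among women -> 5.8%
  expect_equal(
    round_half_up(100 * multi_level_paf(c(0.1697, 0.0341), c(1.25, 1.57)), 1),
    5.8)
  # urban-women vegetable quintiles -> 16.8%
  expect_equal(
    round_half_up(100 * multi_level_paf(rep(0.2, 4), c(1.46, 1.27, 1.18, 1.10)), 1),
    16.8)
  expect_equal(multi_level_paf(rep(0.25, 4), rep(1, 4)), 0)
  expect_error(multi_level_paf(c(0.6, 0.5), c(1.2, 1.3)), "sum")
  expect_error(multi_level_paf(c(-0.1), c(1.2)), "non-negative")
  # exact equivalence with Levin on a single level, over a random grid
  set.seed(42)
  for (i in 1:25) {
    p <- runif(1); rr <- runif(1, 0.5, 3)
    expect_identical(multi_level_paf(p, rr), levin_paf(p, rr))
  }
})

test_that("multi-level PAF equals the closed-form expected-case ratio", {
  # independent oracle: expected cases under observed vs reference exposure
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p <- as.vector(rmultinom(1, 1000, runif(k))) / 1000
    rr <- c(1, runif(k - 1, 1, 2.5))
    r0 <- 0.01
    e_obs <- sum(p * r0 * rr)
    e_ref <- r0
    expect_equal(multi_level_paf(p, rr), (e_obs - e_ref) / e_obs,
                 tolerance = 1e-12)
  }
})

test_that("PAF is monotone in prevalence and in relative risk", {
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(levin_paf(p, 1.5)) > 0))
  rr <- seq(1.05, 3, by = 0.15)
  expect_true(all(diff(levin_paf(0.3, rr)) > 0))
})

test_that("multiplicative combination behaves like joint independent removal", {
  expect_equal(combine_pafs(c(0.5, 0.5)), 0.75)
  expect_equal(combine_pafs(0.3), 0.3)
  # published seven male PAFs -> 49.8%
  male <- c(0.084, 0.087, 0.049, 0.089, 0.188, 0.062, 0.091)
  expect_equal(round_half_up(100 * combine_pafs(male), 1), 49.8)
  expect_error(combine_pafs(c(0.2, 1)), "below 1")
  set.seed(11)
  for (i in 1:20) {
    x <- runif(sample(2:7, 1), 0, 0.5)
    cp <- combine_pafs(x)
    expect_equal(cp, combine_pafs(rev(x)))          # order-invariant
    expect_lte(cp, sum(x))                          # subadditive
    expect_gte(cp, max(x))
    expect_equal(cp, 1 - exp(sum(log(1 - x))))      # log form
  }
})

test_that("region pooling is a weighted mean and robust near w = 1/3", {
  expect_equal(round_half_up(100 * pool_regions(0.0584, 0.0637, 1/3), 1), 6.2)
  expect_equal(pool_regions(0.1, 0.1, 0.77), 0.1)
  expect_error(pool_regions(0.1, 0.2, 1.5), "urban_weight")
  # derived: meat men from quintile PAFs on printed RRs
  u <- multi_level_paf(rep(0.2, 4), c(1.07, 1.12, 1.17, 1.27))
  r <- multi_level_paf(rep(0.2, 4), c(1.04, 1.08, 1.12, 1.20))
  expect_equal(u, 0.1119005, tolerance = 1e-6)
  expect_equal(r, 0.08088235, tolerance = 1e-6)
  expect_equal(round_half_up(100 * pool_regions(u, r, 1/3), 1), 9.1)
})

test_that("attributable counts follow the display-precision rounding policy", {
  # the published table is consistent only with PAF rounded to 3 decimals
  # before multiplication: 79,000 x 0.084 = 6,636, not 79,000 x 0.08411 = 6,645
  paf <- levin_paf(0.574, 1.16)
  expect_identical(attributable_counts(paf, 79000), 6636L)
  expect_identical(attributable_counts(paf, 79000, policy = "exact"), 6645L)
  expect_identical(attributable_counts(0.498, 147000), 73206L)
  expect_identical(attributable_counts(0, 12345), 0L)
  # half-up tie handling at both rounding stages
  expect_identical(attributable_counts(0.0835, 1000), 84L)   # 0.0835 -> 0.084
  expect_identical(attributable_counts(0.1, 1005), 101L)     # 100.5 -> 101
  expect_error(attributable_counts(1.2, 100), "below 1")
})

test_that("sex pooling sums counts and count-weights the PAF", {
  burden <- tibble::tibble(sex = c("male", "female"),
                           deaths = c(79000L, 60000L),
                           incidence = c(147000L, 107000L))
  m <- tibble::tibble(factor = "smoking", paf = 0.084,
                      attributable_deaths = 6636L, attributable_cases = 12348L)
  f <- tibble::tibble(factor = "smoking", paf = 0.004,
                      attributable_deaths = 240L, attributable_cases = 428L)
  tot <- pool_sexes(m, f, burden)
  expect_identical(tot$attributable_deaths, 6876L)
  expect_identical(tot$attributable_cases, 12776L)
  expect_equal(round_half_up(100 * tot$paf, 1), 4.9)
  expect_gte(tot$paf, min(m$paf, f$paf))
  expect_lte(tot$paf, max(m$paf, f$paf))
  f2 <- f; f2$factor <- "alcohol"
  expect_error(pool_sexes(m, f2, burden), "different factors")
  # equal per-sex PAFs pool to themselves under the exact policy
  m2 <- m; f3 <- f
  m2$paf <- f3$paf <- 0.05
  m2$attributable_deaths <- attributable_counts(0.05, 79000, "exact")
  f3$attributable_deaths <- attributable_counts(0.05, 60000, "exact")
  expect_equal(pool_sexes(m2, f3, burden)$paf, 0.05, tolerance = 1e-4)
})

test_that("the packaged study reproduces the published burden table", {
  res <- run_study(fixture_config())
  cell <- function(fct, st) res[res$factor == fct & res$stratum == st, ]
  pct <- function(x) round_half_up(100 * x, 1)

  sm <- cell("tobacco_smoking", "male")
  expect_equal(pct(sm$paf), 8.4)
  expect_identical(sm$attributable_deaths, 6636L)
  expect_identical(sm$attributable_cases, 12348L)
  expect_equal(pct(cell("alcohol_drinking", "male")$paf), 8.7)
  expect_equal(pct(cell("overweight_obesity", "female")$paf), 5.8)
  expect_equal(pct(cell("physical_inactivity", "male")$paf), 8.9)
  expect_equal(pct(cell("low_fruit_intake", "male")$paf), 6.2)
  expect_identical(cell("low_fruit_intake", "male")$attributable_deaths, 4898L)
  expect_equal(pct(cell("high_red_processed_meat_intake", "male")$paf), 9.1)
  expect_equal(pct(cell("high_red_processed_meat_intake", "total")$paf), 8.6)
  expect_identical(cell("alcohol_drinking", "total")$attributable_deaths, 7533L)
  expect_equal(pct(cell("alcohol_drinking", "total")$paf), 5.4)
})

test_that("known non-reproducing cells are flagged, not forced", {
  # the published male vegetable PAF (18.8%) is not recoverable from the
  # published 2-dp quintile RRs: they give 18.5% under any region weight
  res <- run_study(fixture_config())
  veg_m <- res$paf[res$factor == "low_vegetable_intake" & res$stratum == "male"]
  expect_equal(round_half_up(100 * veg_m, 1), 18.5)
  expect_false(round_half_up(100 * veg_m, 1) == 18.8)
  cfg <- fixture_config()
  pub <- cfg$published_pafs
  expect_equal(pub$paf_pct[pub$factor == "low_vegetable_intake" &
                             pub$sex == "male"], 18.8)
})

test_that("run_study rejects protective-coded factors and nulls out RR = 1", {
  cfg <- toy_config()
  cfg$exposure$rr[cfg$exposure$level == "yes"] <- 0.8
  expect_error(run_study(cfg), "RR below 1")
  cfg2 <- toy_config()
  cfg2$exposure$rr <- 1
  cfg2$exposure$rr_lo <- 1
  cfg2$exposure$rr_hi <- 1
  res <- run_study(cfg2)
  expect_true(all(res$paf == 0))
  expect_true(all(res$attributable_deaths == 0L))
  expect_true(all(res$attributable_cases == 0L))
})

test_that("combined rows follow the documented conventions", {
  res <- run_study(fixture_config())
  comb <- res[res$factor == "combined", ]
  per_sex <- res[res$factor != "combined" & res$stratum %in% c("male", "female"), ]
  # combined counts are sums of sex-specific combined counts
  expect_identical(comb$attributable_deaths[comb$stratum == "total"],
                   sum(comb$attributable_deaths[comb$stratum != "total"]))
  # combined per-sex PAF is the multiplicative combination of that sex's
  # display-rounded factor PAFs
  for (sx in c("male", "female")) {
    expected <- combine_pafs(round_half_up(
      per_sex$paf[per_sex$stratum == sx], 3))
    expect_equal(comb$paf[comb$stratum == sx], expected)
  }
  # attributable counts are additive across sexes for every factor
  tot <- res[res$stratum == "total" & res$factor != "combined", ]
  by_sex <- stats::aggregate(attributable_deaths ~ factor, data = per_sex, sum)
  expect_equal(tot$attributable_deaths[match(by_sex$factor, tot$factor)],
               by_sex$attributable_deaths)
})

test_that("results tables round-trip and reject duplicates", {
  res <- run_study(fixture_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))  # 7 factors + combined, 3 strata each
  expect_equal(back$paf_pct, round_half_up(100 * res$paf, 1))
  expect_equal(back$attributable_deaths, res$attributable_deaths)
  dup <- dplyr::bind_rows(res, res[1, ])
  expect_error(write_results_table(dup, path), "duplicate")
  write_results_table(res[0, ], path)
  empty <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("factor", "paf_pct", "attributable_cases") %in% names(empty)))
})
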