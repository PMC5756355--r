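#!/usr/bin/env Rscript
# Reverse-engineer the per-100 g/day dose-response RRs behind the published
# dietary quintile tables, and show the forward transformation reproduces
# the published quintile RRs after 2-dp display rounding.

suppressPackageStartupMessages({
  library(pafburden)
  library(dplyr)
})

cfg <- china_crc_2012()
diet <- c("low_vegetable_intake", "low_fruit_intake",
          "high_red_processed_meat_intake")

rows <- list()
for (fct in diet) {
  harmful <- fct == "high_red_processed_meat_intake"
  for (sx in c("male", "female")) for (rg in c("urban", "rural")) {
    lv <- cfg$exposure |>
      filter(factor == fct, sex == sx, region == rg) |>
      arrange(lower_bound)
    ref <- if (harmful) 1L else nrow(lv)
    beta <- fit_slope_from_levels(lv$lower_bound, lv$rr, ref)
    rebuilt <- quantile_rrs_from_slope(beta, lv$lower_bound, ref, digits = 2)
    rows[[paste(fct, sx, rg)]] <- tibble(
      factor = fct, sex = sx, region = rg,
      rr_per_100g = round(exp(100 * beta), 4),
      quintiles_reproduced = sum(rebuilt == lv$rr),
      quintiles_total = nrow(lv))
  }
}
slopes <- bind_rows(rows)

dir.create("results", showWarnings = FALSE)
readr::write_csv(slopes, "results/dose_response_slopes.csv")

cat("Fitted per-100 g/day RRs and quintile-table agreement:\n")
print(as.data.frame(slopes), row.names = FALSE)
cat("\nThe fitted slopes cluster near 0.91 (vegetable), 0.94 (fruit) and\n")
cat("1.14 (meat) per 100 g/day; these are reconstructions from the published\n")
cat("quintile RRs, not published inputs.\n")
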