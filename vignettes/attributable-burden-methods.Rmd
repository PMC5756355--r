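---
title: "Methods: population attributable fractions and attributable cancer burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population attributable fractions and attributable cancer burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafburden)
```

## The problem

Comparative risk assessment asks what share of a disease burden would
disappear if the population's exposure to a risk factor were shifted to a
reference level. `pafburden` implements this for the classic
cross-sectional design: exposure prevalences from national surveys,
relative risks (RRs) from cohort studies and meta-analyses, and total
deaths and incident cases from a cancer registry projection. The packaged
worked example is the burden of colorectal cancer in China in 2012
attributable to seven lifestyle factors: tobacco smoking, alcohol
drinking, overweight/obesity, physical inactivity, low vegetable intake,
low fruit intake, and high red and processed meat intake.

## The model

**Binary exposures.** For prevalence $P$ and relative risk $RR$, Levin's
formula gives the population attributable fraction

$$PAF = \frac{P\,(RR - 1)}{P\,(RR - 1) + 1}.$$

**Categorised exposures.** Dietary intakes are split into quintiles, each
holding 20% of the population, and the counterfactual is a *full shift*:
everyone moves to the most favourable quintile (the top quintile for
protective intakes, the bottom for harmful ones), which serves as the
reference with $RR = 1$. Then

$$PAF = \frac{\sum_i P_i (RR_i - 1)}{\sum_i P_i (RR_i - 1) + 1},$$

which reduces to Levin's formula when only one non-reference level exists.
An equivalent reading — used as the package's independent test oracle — is
the expected-case comparison: with baseline risk $r_0$, expected cases are
$E_{obs} = \sum_i P_i\, r_0\, RR_i$ under observed exposure and
$E_{ref} = r_0$ under the counterfactual, and
$PAF = (E_{obs} - E_{ref})/E_{obs}$ exactly.

**Combination across factors.** Assuming the factors act independently and
multiplicatively,

$$PAF_{joint} = 1 - \prod_k (1 - PAF_k).$$

This is order-invariant, never exceeds the sum of its inputs, and never
falls below their maximum. No interaction or exposure-correlation
adjustment is attempted.

**Dose-response categorisation.** Dietary RRs originate as log-linear
slopes per 100 g/day. `log_slope_per_gram()` converts the published
per-100 g RR to $\beta = \ln(RR_{100})/100$;
`quantile_rrs_from_slope()` evaluates $\exp\{\beta(L_i - L_{ref})\}$ at
each quintile's *lower intake bound* $L_i$ (the bottom quintile's bound is
0) and rescales so the reference quintile is exactly 1. Representing a
quintile by its lower bound, rather than its midpoint, is deliberate: it
is the only reading under which the published quintile RR tables are
reproduced by the forward transformation (verified for every dietary
factor, sex and region; see `analysis/03_dose_response.R`).
`fit_slope_from_levels()` inverts the transformation by least squares of
$\ln RR_i$ on $L_i - L_{ref}$ through the origin; the packaged quintile
tables invert to roughly 0.91 (vegetable), 0.94 (fruit) and 1.14 (meat)
per 100 g/day. These slopes are reconstructions — the source per-100 g RRs
are not part of the packaged inputs.

**Attributable counts and pooling.** Attributable deaths (cases) are
$PAF \times$ total deaths (cases) in the stratum. The default policy
rounds the PAF to three decimals — one decimal in percent, the display
precision — *before* multiplying, then rounds half-up to an integer. This
is the convention under which the packaged burden table is internally
consistent: $79{,}000 \times 0.084 = 6{,}636$, whereas the unrounded
$0.08411$ would give $6{,}645$. Sex pooling sums attributable counts and
divides by total deaths, so the pooled PAF always lies between the per-sex
PAFs. The combined (all-factor) totals follow two conventions at once,
reproduced as is: combined counts are sums of sex-specific combined
counts, while the combined total PAF is the multiplicative combination of
the factor-level total PAFs — the two disagree by design in the source
analysis (63,102/139,000 = 45.4% vs the printed 45.5%), and the package
does not reconcile them.

## Uncertainty

The RR sampling distribution is taken as lognormal, the standard choice
for ratio measures, with $\sigma_{\ln RR} = (\ln hi - \ln lo)/(2z)$
recovered from the published CI. Two propagation routes are provided:

* **Delta method** (`paf_ci_delta()`): first-order Taylor expansion of
  Levin's formula, $var(PAF) \approx (\partial PAF/\partial RR)^2
  (RR\,\sigma_{\ln RR})^2 + (\partial PAF/\partial P)^2 \sigma_P^2$, with
  $\partial PAF/\partial RR = P/D^2$, $\partial PAF/\partial P =
  (RR-1)/D^2$, $D = 1 + P(RR-1)$. Prevalence uncertainty defaults to zero
  (survey sizes are large and the published intervals appear RR-driven);
  a binomial $\sigma_P$ can be supplied. For multi-level factors the
  natural extension $var = \sum_i (P_i/D^2)^2 (RR_i \sigma_i)^2$ is used;
  regions, sexes and factors are treated as independent — an
  approximation, since several RRs are shared across strata.
* **Monte Carlo** (`paf_ci_mc()`, and `run_study(ci = "mc")` for the
  combined rows the delta formula does not cover): draw
  $\ln RR_i \sim N(\ln rr_i, \sigma_i)$ independently, recompute the PAF
  per draw, report percentile intervals. Deterministic per seed.

The two routes agree within 10% relative half-width on binary factors
across the realistic grid $P \in [0.01, 0.6]$, $RR \in [1.05, 2]$ (a
property test). Published interval bounds are *not* reproduction targets:
the source's exact delta variant is unstated, and several printed
intervals (e.g. a total-column interval wider than both per-sex
intervals) are not recoverable from any standard formula tried.

## The packaged study configuration

`china_crc_2012()` loads the packaged inputs: seven factors, exposure
prevalence and RRs by sex (and urban/rural region for the dietary
factors), quintile intake cutpoints in g/day, and the 2012 burden —
79,000/60,000 deaths and 147,000/107,000 incident cases (men/women). The
sex-specific incidence values are used because the burden table's
arithmetic requires them, even though the abstract-level incidence is
quoted slightly lower. Notable conventions preserved from the source
analysis rather than "corrected":

* Smoking pairs ever-smoker prevalence (57.4% men, 2.6% women) with the
  current-vs-never RR of 1.16.
* Dietary quintile RRs are the published 2-decimal values
  (`use_printed_rrs`); full-precision slope-derived RRs shift third-decimal
  digits.
* Quintile prevalences are fixed at 0.2 by construction and stored
  explicitly.

**Urban weight.** The per-sex dietary PAFs pool urban and rural quintile
PAFs by a weighted arithmetic mean. The source states no pooling rule; the
default weight of 1/3 urban is a calibration that reproduces the male
fruit (6.2%) and male/female meat (9.1%/7.9%) cells and is robust across
weights in [0.30, 0.40]. It is configurable via
`run_study(urban_weight = )`.

**Known non-reproductions.** Three published dietary cells cannot be
derived from the published quintile RRs under any pooling weight: male
vegetable prints 18.8% where the RRs give 18.5%; female vegetable prints
16.8% vs 16.9% computed; female fruit prints 6.7% where urban and rural
computations give 6.5% and 8.9% (so no weight in [0,1] reaches 6.7%). The
source presumably combined unrounded transformed RRs or a different
female-fruit input. The package reports its computed values and asserts
the discrepancy in tests instead of forcing agreement. Downstream, the
published combined figures (49.8%/39.6%/45.5%, 63,102 deaths, 115,578
cases) therefore reproduce exactly when the combination formulas are fed
the published per-factor PAFs — shipped as `published_pafs.csv` in the
fixture — while the fully end-to-end pipeline lands nearby
(49.7%/40.6%/45.8%, 63,623 deaths). Both routes are computed and tested.

## Synthetic data

The generator (`synthetic_config()` and friends) emulates the study's
data-collection layer with known ground truth:

* **Surveys**: multinomial draws of `survey_n` individuals per
  factor-stratum at the true prevalences (Bernoulli in the binary case),
  mirroring multi-stage cross-sectional prevalence surveys. The default
  `survey_n = 50,000` is of the order of the national surveys behind the
  packaged prevalences (14,933–240,000 participants).
* **Population oracle**: a finite population (default $10^6$) with
  baseline risk $r_0 = 0.01$ — a realistic cumulative colorectal-cancer
  risk scale — where each individual draws an exposure level and the
  empirical PAF is $1 - E_{ref}/E_{obs}$ by expected-value comparison.
  Expected-value (rather than per-individual case) comparison removes the
  binomial case-draw noise, leaving only multinomial exposure noise, so
  the oracle converges to the closed form at rate $n^{-1/2}$.
* **Streams**: every draw is seeded by a deterministic hash of
  `(seed, factor, sex, region)`, so adding a factor never perturbs the
  other factors' draws.

Recovery is judged at 3 delta-propagated multinomial standard errors.
What passing recovery shows: the pipeline is an unbiased, correctly-wired
estimator of the generating PAFs under the model's own assumptions. What
it does not show: robustness to correlated exposures, confounding,
exposure measurement error, or induction-time misspecification — none of
which the generator simulates.

## Numerical choices

* Counts round half-up (ties away from zero), not half-to-even; PAF
  display rounding is half-up at one decimal percent.
* The reference entry of a reconstructed RR vector is set to exactly 1,
  immune to floating-point drift.
* Delta intervals truncate to $[0, 1)$; Monte-Carlo draws that take an RR
  below 1 during study-level simulation are clipped at 1, matching the
  pipeline's requirement that exposures be coded harmful.
* `run_study()` rejects factors whose non-reference RR is below 1 with an
  instruction to recode, rather than silently producing negative PAFs;
  the raw formulas (`levin_paf()`) do allow negative values.
* Combination uses display-rounded (3-decimal) per-factor PAFs, matching
  the count convention.
* Default problem sizes — $10^6$ for the population oracle, 50,000 per
  simulated survey, 5,000–20,000 Monte-Carlo draws — keep every analysis
  script and the full test suite in the seconds-to-a-couple-of-minutes
  range on a single CPU while leaving Monte-Carlo error well inside the
  tolerances tested.

## Limitations

* Independence across factors is assumed in the combination formula; the
  joint PAF is therefore an upper-bound-flavoured approximation when
  exposures cluster.
* CIs assume independent RRs across levels, regions, sexes and factors;
  shared meta-analytic RRs violate this mildly.
* The urban weight is a calibrated, not measured, quantity.
* Prevalence uncertainty is ignored by default.
* The dose-response model is log-linear; nonlinear shapes are out of
  scope.
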