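#' Read and validate a study configuration
#'
#' A study is described by a JSON skeleton naming the factors (with their
#' `kind` — `binary`, `multi_level` or `quantile_dose_response` — and
#' `direction`), the pooling weights, and the CSV tables it references:
#' an exposure table (`factor,kind,sex,region,level,prevalence,rr,rr_lo,
#' rr_hi,is_reference,lower_bound`), a burden table (`sex,deaths,incidence`)
#' and optionally a table of published per-factor PAF point estimates
#' (`factor,sex,paf_pct`) for comparison and for combination-stage inputs.
#' Paths inside the JSON are resolved relative to its directory. All type
#' invariants are checked on read; violations raise an error naming the
#' offending record and rule.
#'
#' @param path Path to the study JSON file.
#' @return A validated `study_config` object (a list with elements `name`,
#'   `factors`, `factor_names`, `exposure`, `burden`, `pooling`, `z`,
#'   `use_printed_rrs`, and `published_pafs` if supplied).
#' @seealso [china_crc_2012()] for the packaged configuration,
#'   [write_study_config()] for the inverse.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  skel <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  tab <- function(name) {
    f <- file.path(dir, skel$tables[[name]])
    if (!file.exists(f)) stop("referenced table not found: ", f, call. = FALSE)
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  exposure <- tab("exposure")
  burden <- tab("burden")
  published <- if (!is.null(skel$tables$published_pafs)) tab("published_pafs")
  config <- structure(list(
    name = skel$name,
    factors = tibble::as_tibble(skel$factors),
    factor_names = skel$factors$name,
    exposure = exposure,
    burden = burden,
    pooling = as.list(skel$pooling),
    z = skel$z %||% 1.96,
    use_printed_rrs = isTRUE(skel$use_printed_rrs),
    published_pafs = published
  ), class = "study_config")
  validate_study_config(config)
  config
}

#' Validate a study configuration
#'
#' Checks every structural invariant: prevalences in \[0, 1\] and summing to 1
#' within each factor-sex-region stratum; RRs positive with CIs bracketing the
#' point estimate; exactly one reference level (RR = 1) per stratum; binary
#' factors with exactly one non-reference level; quantile factors with
#' strictly increasing lower bounds starting at 0; non-negative burden counts;
#' pooling weights in \[0, 1\].
#'
#' @param config A `study_config`.
#' @return `config`, invisibly, if valid; otherwise an error whose message
#'   names the record and the violated rule.
#' @export
validate_study_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ex <- config$exposure
  need <- c("factor", "sex", "region", "level", "prevalence", "rr",
            "rr_lo", "rr_hi", "is_reference")
  missing_cols <- setdiff(need, names(ex))
  if (length(missing_cols))
    stop("exposure table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (length(config$factor_names) == 0)
    stop("factor list is empty", call. = FALSE)
  rec <- function(i) paste0("[", ex$factor[i], "/", ex$sex[i], "/",
                            ex$region[i], "/", ex$level[i], "]")
  bad <- which(ex$prevalence < 0 | ex$prevalence > 1)
  if (length(bad))
    stop("record ", rec(bad[1]), ": prevalence ", ex$prevalence[bad[1]],
         " outside [0, 1]", call. = FALSE)
  bad <- which(ex$rr <= 0 | ex$rr_lo <= 0)
  if (length(bad))
    stop("record ", rec(bad[1]), ": relative risk must be positive",
         call. = FALSE)
  bad <- which(ex$rr_lo > ex$rr | ex$rr > ex$rr_hi)
  if (length(bad))
    stop("record ", rec(bad[1]), ": CI (", ex$rr_lo[bad[1]], ", ",
         ex$rr_hi[bad[1]], ") does not bracket RR ", ex$rr[bad[1]],
         call. = FALSE)
  if (!all(ex$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(ex$region %in% c("national", "urban", "rural")))
    stop("region must be 'national', 'urban' or 'rural'", call. = FALSE)

  kinds <- stats::setNames(config$factors$kind, config$factors$name)
  for (key in split(seq_len(nrow(ex)),
                    paste(ex$factor, ex$sex, ex$region, sep = "/"))) {
    sub <- ex[key, ]
    id <- paste0("[", sub$factor[1], "/", sub$sex[1], "/", sub$region[1], "]")
    n_ref <- sum(sub$is_reference)
    if (n_ref != 1)
      stop("stratum ", id, ": needs exactly one reference level, found ",
           n_ref, call. = FALSE)
    if (any(sub$rr[sub$is_reference] != 1))
      stop("stratum ", id, ": reference level must carry RR = 1", call. = FALSE)
    if (abs(sum(sub$prevalence) - 1) > 1e-9)
      stop("stratum ", id, ": level prevalences sum to ",
           sum(sub$prevalence), ", not 1", call. = FALSE)
    kind <- kinds[[sub$factor[1]]]
    if (identical(kind, "binary") && sum(!sub$is_reference) != 1)
      stop("stratum ", id, ": binary factor must have exactly one ",
           "non-reference level", call. = FALSE)
    if (identical(kind, "quantile_dose_response")) {
      lb <- sub$lower_bound[order(sub$lower_bound)]
      if (anyNA(lb) || lb[1] != 0 || any(diff(lb) <= 0))
        stop("stratum ", id, ": quantile lower bounds must start at 0 and ",
             "be strictly increasing", call. = FALSE)
    }
  }
  b <- config$burden
  if (!all(c("sex", "deaths", "incidence") %in% names(b)))
    stop("burden table needs columns sex, deaths, incidence", call. = FALSE)
  if (any(b$deaths < 0 | b$incidence < 0))
    stop("burden counts must be non-negative", call. = FALSE)
  w <- config$pooling$urban_weight
  if (!is.null(w) && (w < 0 || w > 1))
    stop("pooling urban_weight ", w, " outside [0, 1]", call. = FALSE)
  invisible(config)
}

#' Write a study configuration to disk
#'
#' Inverse of [read_study_config()]: writes `study.json` plus the referenced
#' CSV tables into `dir`. A written configuration reads back identical.
#'
#' @param config A `study_config`.
#' @param dir Output directory (created if absent).
#' @return The path to the written `study.json`, invisibly.
#' @export
write_study_config <- function(config, dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(config$exposure, file.path(dir, "exposure.csv"), progress = FALSE)
  readr::write_csv(config$burden, file.path(dir, "burden.csv"), progress = FALSE)
  tables <- list(exposure = "exposure.csv", burden = "burden.csv")
  if (!is.null(config$published_pafs)) {
    readr::write_csv(config$published_pafs,
                     file.path(dir, "published_pafs.csv"), progress = FALSE)
    tables$published_pafs <- "published_pafs.csv"
  }
  skel <- list(name = config$name, z = config$z,
               use_printed_rrs = config$use_printed_rrs,
               pooling = config$pooling, factors = config$factors,
               tables = tables)
  path <- file.path(dir, "study.json")
  jsonlite::write_json(skel, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' The China 2012 colorectal cancer study configuration
#'
#' Packaged inputs for the attributable burden of colorectal cancer in China
#' in 2012: seven risk factors (tobacco smoking, alcohol drinking,
#' overweight/obesity, physical inactivity, low vegetable intake, low fruit
#' intake, high red and processed meat intake), their national or
#' urban/rural-by-sex exposure prevalences and relative risks, quintile
#' intake cutpoints (g/day) for the dietary factors, the Globocan 2012
#' deaths and incident cases by sex, and the published per-factor PAF point
#' estimates. Dietary quintile RRs are the published 2-decimal values
#' (`use_printed_rrs`); sex-specific incident cases (147,000 men, 107,000
#' women) are used because the burden table's arithmetic requires them.
#'
#' The smoking factor intentionally pairs ever-smoker prevalence (57.4% men,
#' 2.6% women) with the current-vs-never RR 1.16, the convention of the
#' source analysis; it is preserved, not corrected.
#'
#' @return A validated `study_config`.
#' @examples
#' cfg <- china_crc_2012()
#' cfg$factor_names
#' @export
china_crc_2012 <- function() {
  read_study_config(system.file("extdata", "china_crc_2012", "study.json",
                                package = "pafburden", mustWork = TRUE))
}

#' Write a results table
#'
#' Writes PAF estimates in a layout mirroring a published burden table:
#' columns `factor`, `stratum`, `paf_pct`, `ci_low_pct`, `ci_high_pct`,
#' `attributable_deaths`, `attributable_cases`, percentages rounded half-up
#' to one decimal. An empty input produces a header-only file.
#'
#' @param estimates Tibble as returned by [run_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(estimates, path) {
  cols <- c("factor", "stratum", "paf_pct", "ci_low_pct", "ci_high_pct",
            "attributable_deaths", "attributable_cases")
  if (is.null(estimates) || length(estimates) == 0 || nrow(estimates) == 0) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    readr::write_csv(empty, path, progress = FALSE)
    return(invisible(path))
  }
  need <- c("factor", "stratum", "paf", "attributable_deaths",
            "attributable_cases")
  stopifnot(all(need %in% names(estimates)))
  if (nrow(estimates) > 0 &&
      anyDuplicated(estimates[, c("factor", "stratum")]))
    stop("duplicate (factor, stratum) rows in estimates", call. = FALSE)
  pct <- function(x) round_half_up(100 * x, 1)
  out <- tibble::tibble(
    factor = estimates$factor,
    stratum = estimates$stratum,
    paf_pct = pct(estimates$paf),
    ci_low_pct = if ("ci_low" %in% names(estimates)) pct(estimates$ci_low) else NA_real_,
    ci_high_pct = if ("ci_high" %in% names(estimates)) pct(estimates$ci_high) else NA_real_,
    attributable_deaths = estimates$attributable_deaths,
    attributable_cases = estimates$attributable_cases
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
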