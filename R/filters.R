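#' Study eligibility configuration
#'
#' Thresholds and toggles for the cohort eligibility rules: exclusion of
#' same-day multiple initiations, therapies started less than 61 days after a
#' previous therapy, first-line initiations, insulin co-treatment, end-stage
#' renal disease, missing baseline HbA1c, baseline HbA1c below 53 mmol/mol
#' (7%), and missing outcome HbA1c.
#'
#' @param min_baseline_hba1c Minimum baseline HbA1c in mmol/mol; rows strictly
#'   below are excluded (default 53).
#' @param min_days_since_prior_start Minimum days since the start of a
#'   previous therapy (default 61; rows strictly below are excluded).
#' @param outcome_window Outcome ascertainment window in months,
#'   `c(lower, upper)` (default `c(3, 15)`), inclusive.
#' @param outcome_target Target outcome month (default 12).
#' @param require_outcome Exclude rows with missing outcome HbA1c.
#' @param first_line_excluded,insulin_excluded,esrd_excluded Rule toggles.
#' @return An object of class `eligibility_config`.
#' @export
eligibility_config <- function(min_baseline_hba1c = 53,
                               min_days_since_prior_start = 61,
                               outcome_window = c(3, 15),
                               outcome_target = 12,
                               require_outcome = TRUE,
                               first_line_excluded = TRUE,
                               insulin_excluded = TRUE,
                               esrd_excluded = TRUE) {
  assert_that(min_baseline_hba1c > 0 && min_days_since_prior_start > 0,
              "thresholds must be positive")
  assert_that(outcome_window[1] < outcome_target &&
                outcome_target < outcome_window[2],
              "outcome window must satisfy lower < target < upper")
  structure(list(min_baseline_hba1c = min_baseline_hba1c,
                 min_days_since_prior_start = min_days_since_prior_start,
                 outcome_window = outcome_window,
                 outcome_target = outcome_target,
                 require_outcome = require_outcome,
                 first_line_excluded = first_line_excluded,
                 insulin_excluded = insulin_excluded,
                 esrd_excluded = esrd_excluded),
            class = "eligibility_config")
}

#' Apply the study eligibility rules
#'
#' Rules are applied in a fixed order: same-day multiple initiation, the
#' 61-day rule, first-line initiation, insulin co-treatment, end-stage renal
#' disease, missing baseline HbA1c, baseline HbA1c < 53 mmol/mol (strict),
#' and missing outcome HbA1c. A row with baseline HbA1c exactly at the
#' threshold is retained. The per-rule exclusion counts depend on this order;
#' the total number excluded does not.
#'
#' @param raw A cohort tibble with the flag and value columns the rules read.
#' @param cfg An [eligibility_config()].
#' @return A list with `cohort` (the eligible rows) and `log`, a `FilterLog`
#'   tibble with one row per rule: `rule`, `n_excluded`, `n_remaining`.
#' @export
apply_eligibility <- function(raw, cfg = eligibility_config()) {
  rules <- list(
    list(name = "same-day multiple initiation",
         active = TRUE,
         drop = function(d) !is.na(d$same_day_multi) & d$same_day_multi == 1),
    list(name = sprintf("< %d days since prior therapy start",
                        cfg$min_days_since_prior_start),
         active = TRUE,
         drop = function(d) !is.na(d$days_since_prior_start) &
           d$days_since_prior_start < cfg$min_days_since_prior_start),
    list(name = "first-line initiation",
         active = cfg$first_line_excluded,
         drop = function(d) !is.na(d$first_line) & d$first_line == 1),
    list(name = "insulin co-treatment",
         active = cfg$insulin_excluded,
         drop = function(d) !is.na(d$insulin) & d$insulin == 1),
    list(name = "end-stage renal disease",
         active = cfg$esrd_excluded,
         drop = function(d) !is.na(d$esrd) & d$esrd == 1),
    list(name = "missing baseline HbA1c",
         active = TRUE,
         drop = function(d) is.na(d$hba1c_baseline)),
    list(name = sprintf("baseline HbA1c < %s mmol/mol", cfg$min_baseline_hba1c),
         active = TRUE,
         drop = function(d) !is.na(d$hba1c_baseline) &
           d$hba1c_baseline < cfg$min_baseline_hba1c),
    list(name = "missing outcome HbA1c",
         active = cfg$require_outcome,
         drop = function(d) is.na(d$outcome_hba1c))
  )
  needed <- c("same_day_multi", "days_since_prior_start", "first_line",
              "insulin", "esrd", "hba1c_baseline", "outcome_hba1c")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))

  cohort <- raw
  log <- tibble::tibble(rule = character(), n_excluded = integer(),
                        n_remaining = integer())
  for (rl in rules) {
    if (!rl$active) next
    drop <- rl$drop(cohort)
    cohort <- cohort[!drop, , drop = FALSE]
    log <- dplyr::bind_rows(log, tibble::tibble(
      rule = rl$name, n_excluded = sum(drop), n_remaining = nrow(cohort)))
  }
  list(cohort = cohort, log = log)
}

#' Write a filter log as structured text
#'
#' @param log A `FilterLog` tibble from [apply_eligibility()].
#' @param path File path.
#' @export
write_filter_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' Ascertain the primary outcome from repeat measurements
#'
#' The primary outcome is the HbA1c measurement closest to the target month
#' (12) within the ascertainment window (3-15 months, bounds inclusive).
#' Ties at equal distance from the target go to the earlier month.
#'
#' @param measurements A data frame (or tibble) with columns `month` and
#'   `hba1c`, or a list of `c(month, hba1c)` pairs.
#' @param window Inclusive window in months.
#' @param target Target month.
#' @return A one-row tibble with `hba1c` and `month`, or `NULL` if no
#'   measurement falls in the window.
#' @export
ascertain_outcome <- function(measurements, window = c(3, 15), target = 12) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- tibble::tibble(
      month = vapply(measurements, `[[`, numeric(1), 1),
      hba1c = vapply(measurements, `[[`, numeric(1), 2))
  if (nrow(measurements) == 0) return(NULL)
  assert_that(all(measurements$month >= 0), "months must be non-negative")
  ok <- measurements$month >= window[1] & measurements$month <= window[2]
  m <- measurements[ok, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  dist <- abs(m$month - target)
  # ties at equal distance resolve toward the earlier month
  best <- order(dist, m$month)[1]
  tibble::tibble(hba1c = m$hba1c[best], month = m$month[best])
}

#' Stratified development/validation split
#'
#' Randomly splits a cohort into development and validation sets, maintaining
#' the proportion of individuals receiving each drug class. Per-stratum
#' development counts are `round-half-up(fraction * stratum size)`.
#'
#' @param cohort A cohort tibble with a `drugclass` column.
#' @param dev_fraction Development fraction in (0, 1); default 0.6.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return A list with `development` and `validation` tibbles; disjoint and
#'   exhaustive.
#' @export
split_dev_val <- function(cohort, dev_fraction = 0.6, seed) {
  assert_that(nrow(cohort) > 0, "cannot split an empty cohort")
  assert_that(dev_fraction > 0 && dev_fraction < 1,
              "`dev_fraction` must be in (0, 1)")
  assert_that(!missing(seed), "`seed` is required")
  set.seed(seed)
  dev_idx <- logical(nrow(cohort))
  for (g in unique(cohort$drugclass)) {
    rows <- which(cohort$drugclass == g)
    n_dev <- floor(dev_fraction * length(rows) + 0.5)  # round half up
    dev_idx[sample(rows, n_dev)] <- TRUE
  }
  list(development = cohort[dev_idx, , drop = FALSE],
       validation = cohort[!dev_idx, , drop = FALSE])
}

#' Complete-case restriction
#'
#' Drops rows with any missing value among the given predictors (the fitted
#' models cannot handle missing data, so analysis is complete-case).
#'
#' @param cohort A cohort tibble.
#' @param predictor_set Character vector of column names.
#' @return The cohort restricted to complete cases.
#' @export
complete_cases <- function(cohort, predictor_set) {
  missing_cols <- setdiff(predictor_set, names(cohort))
  if (length(missing_cols) > 0)
    abort(paste0("predictor_set contains unknown column(s): ",
                 paste(missing_cols, collapse = ", ")))
  keep <- complete.cases(cohort[, predictor_set, drop = FALSE])
  cohort[keep, , drop = FALSE]
}
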