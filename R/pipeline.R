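#' Configuration of the end-to-end analysis pipeline
#'
#' Bundles every stage's settings. Each stochastic stage derives its seed
#' deterministically from the global `seed` and the stage name, so a full run
#' is reproducible and any stage can be re-run from the persisted artifacts
#' of its upstream stage with identical results.
#'
#' @param out_dir Output directory for artifacts and the run report.
#' @param seed Global integer seed.
#' @param generator A [generator_config()] (its seed is overridden by the
#'   stage seed).
#' @param eligibility An [eligibility_config()].
#' @param propensity A [propensity_config()] (seed overridden).
#' @param bcf A [bcf_config()] for the selection fit (sparsity is forced on;
#'   seed overridden).
#' @param bcf_final A [bcf_config()] for the final parsimonious fit; defaults
#'   to `bcf` with twice the iterations (the small predictor set mixes more
#'   slowly through the effect-surface scale).
#' @param tau_predictors,mu_predictors Candidate predictor sets.
#' @param dev_fraction Development fraction of the stratified split.
#' @param validation_k Number of predicted-CATE bins for calibration
#'   (10 deciles; use 5 quintiles for small cohorts).
#' @param benefit_thresholds Benefit subgroup thresholds in mmol/mol.
#' @param stages Stages to run, in order.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       generator = generator_config(n = 5000),
                       eligibility = eligibility_config(),
                       propensity = propensity_config(),
                       bcf = bcf_config(),
                       bcf_final = NULL,
                       tau_predictors = full_predictor_set(),
                       mu_predictors = mu_predictor_set(),
                       dev_fraction = 0.6,
                       validation_k = 10,
                       benefit_thresholds = c(3, 5),
                       stages = c("simulate", "filter", "propensity", "fit",
                                  "select", "predict", "validate",
                                  "secondary", "report")) {
  structure(as.list(environment()), class = "run_config")
}

art <- function(config, ...) file.path(config$out_dir, ...)

write_manifest <- function(config, stage, info) {
  info$stage <- stage
  info$seed <- stage_seed(config$seed, stage)
  info$config_snapshot <- utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")], give.attr = FALSE))
  jsonlite::write_json(info, art(config, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

need_artifact <- function(config, file, stage) {
  p <- art(config, file)
  if (!file.exists(p))
    abort(paste0("missing upstream artifact `", file, "`; run stage `",
                 stage, "` first"))
  p
}

#' Run a single pipeline stage from persisted artifacts
#'
#' @param config A [run_config()].
#' @param stage Stage name, one of `simulate`, `filter`, `propensity`, `fit`,
#'   `select`, `predict`, `validate`, `secondary`, `report`.
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(config, stage) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(stage,
    simulate = stage_simulate(config),
    filter = stage_filter(config),
    propensity = stage_propensity(config),
    fit = stage_fit(config),
    select = stage_select(config),
    predict = stage_predict(config),
    validate = stage_validate(config),
    secondary = stage_secondary(config),
    report = stage_report(config),
    abort(paste0("unknown stage `", stage, "`")))
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

stage_simulate <- function(config) {
  gen <- config$generator
  gen$seed <- stage_seed(config$seed, "simulate")
  cohort <- generate_cohort(gen)
  write_cohort(cohort, art(config, "cohort.csv"))
  write_generator_config(gen, art(config, "generator_config.yaml"))
  write_manifest(config, "simulate", list(n = nrow(cohort)))
  cohort
}

stage_filter <- function(config) {
  cohort <- read_cohort(need_artifact(config, "cohort.csv", "simulate"))
  elig <- apply_eligibility(cohort, config$eligibility)
  preds <- union(config$mu_predictors, config$tau_predictors)
  eligible <- complete_cases(elig$cohort, preds)
  split <- split_dev_val(eligible, config$dev_fraction,
                         seed = stage_seed(config$seed, "filter"))
  write_filter_log(elig$log, art(config, "filter_log.csv"))
  write_cohort(split$development, art(config, "development.csv"))
  write_cohort(split$validation, art(config, "validation.csv"))
  write_manifest(config, "filter", list(
    n_raw = nrow(cohort), n_eligible = nrow(elig$cohort),
    n_complete = nrow(eligible), n_development = nrow(split$development),
    n_validation = nrow(split$validation)))
  split
}

stage_propensity <- function(config) {
  dev <- read_cohort(need_artifact(config, "development.csv", "filter"))
  val <- read_cohort(need_artifact(config, "validation.csv", "filter"))
  pcfg <- config$propensity
  pcfg$seed <- stage_seed(config$seed, "propensity")
  pfit <- fit_propensity(dev, config$tau_predictors, pcfg)
  readr::write_csv(tibble::tibble(id = dev$id, pihat = pfit$pihat),
                   art(config, "pihat_development.csv"))
  readr::write_csv(tibble::tibble(id = val$id,
                                  pihat = predict(pfit, val)),
                   art(config, "pihat_validation.csv"))
  saveRDS(pfit, art(config, "propensity_fit.rds"))
  write_manifest(config, "propensity", list(n = pfit$n, auc = pfit$auc))
  pfit
}

stage_fit <- function(config) {
  dev <- read_cohort(need_artifact(config, "development.csv", "filter"))
  pihat <- readr::read_csv(
    need_artifact(config, "pihat_development.csv", "propensity"),
    show_col_types = FALSE)$pihat
  bcfg <- config$bcf
  bcfg$sparsity <- TRUE  # selection fit needs splitting probabilities
  bcfg$seed <- stage_seed(config$seed, "fit")
  fit <- fit_bcf(dev, config$mu_predictors, config$tau_predictors,
                 pihat = pihat, config = bcfg)
  write_bcf_posterior(fit, art(config, "posterior_selection"))
  write_manifest(config, "fit", list(
    n = fit$n, n_draws = ncol(fit$mu), sigma = mean(fit$sigma)))
  fit
}

stage_select <- function(config) {
  fit <- read_bcf_posterior(need_artifact(config, "posterior_selection",
                                          "fit"))
  sel <- select_variables(fit)
  readr::write_csv(tibble::as_tibble(sel), art(config, "selection.csv"))
  write_manifest(config, "select", list(
    n_selected_prognostic = sum(sel$selected[sel$forest == "prognostic"]),
    n_selected_effect = sum(sel$selected[sel$forest == "effect"])))
  sel
}

stage_predict <- function(config) {
  dev <- read_cohort(need_artifact(config, "development.csv", "filter"))
  val <- read_cohort(need_artifact(config, "validation.csv", "filter"))
  pihat_dev <- readr::read_csv(
    need_artifact(config, "pihat_development.csv", "propensity"),
    show_col_types = FALSE)$pihat
  pihat_val <- readr::read_csv(
    need_artifact(config, "pihat_validation.csv", "propensity"),
    show_col_types = FALSE)$pihat
  sel <- readr::read_csv(need_artifact(config, "selection.csv", "select"),
                         show_col_types = FALSE)
  mu_sel <- sel$variable[sel$forest == "prognostic" & sel$selected]
  tau_sel <- sel$variable[sel$forest == "effect" & sel$selected]
  pihat_selected <- "pihat" %in% mu_sel
  mu_sel <- union(setdiff(mu_sel, "pihat"), "outcome_month")
  if (length(tau_sel) == 0) tau_sel <- config$tau_predictors
  bcfg <- config$bcf_final
  if (is.null(bcfg)) {
    bcfg <- config$bcf
    bcfg$n_iter <- 2 * bcfg$n_iter - bcfg$n_burn
  }
  bcfg$sparsity <- FALSE
  bcfg$include_pihat_in_mu <- pihat_selected
  bcfg$seed <- stage_seed(config$seed, "predict")
  final <- fit_bcf(dev, mu_sel, tau_sel,
                   pihat = if (pihat_selected) pihat_dev else NULL,
                   config = bcfg)
  write_bcf_posterior(final, art(config, "posterior_final"))
  cate_dev <- predict_cate(final)
  nd <- val
  nd$pihat <- pihat_val
  cate_val <- predict_cate(final, newdata = nd)
  readr::write_csv(tibble::as_tibble(cate_dev), art(config, "cate_development.csv"))
  readr::write_csv(tibble::as_tibble(cate_val), art(config, "cate_validation.csv"))
  imp <- best_linear_projection(cate_dev,
                                dev[, config$tau_predictors, drop = FALSE])
  readr::write_csv(imp, art(config, "importance.csv"))
  write_manifest(config, "predict", list(
    n_development = nrow(cate_dev), n_validation = nrow(cate_val),
    mu_predictors = mu_sel, tau_predictors = tau_sel,
    pihat_selected = pihat_selected))
  list(fit = final, cate_development = cate_dev, cate_validation = cate_val,
       importance = imp)
}

stage_validate <- function(config) {
  val <- read_cohort(need_artifact(config, "validation.csv", "filter"))
  cate <- readr::read_csv(need_artifact(config, "cate_validation.csv",
                                        "predict"), show_col_types = FALSE)
  pihat <- readr::read_csv(
    need_artifact(config, "pihat_validation.csv", "propensity"),
    show_col_types = FALSE)$pihat
  k <- min(config$validation_k, nrow(val))
  bins <- decile_bins(cate, k = k)
  pred_by_bin <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bins, cate = cate$cate_mean),
                    .data$bin),
    predicted_cate = mean(.data$cate), .groups = "drop")
  ates <- dplyr::bind_rows(lapply(sort(unique(bins)), function(b)
    subgroup_ate_regression(val, bins == b,
                            covariates = config$tau_predictors,
                            subgroup = b)))
  ates$bin <- ates$subgroup
  calib <- calibration_summary(pred_by_bin, ates)
  readr::write_csv(calib$table, art(config, "calibration.csv"))
  smd <- smd_table(val, config$tau_predictors)
  readr::write_csv(smd, art(config, "smd.csv"))
  m <- ps_match(pihat, val$drugclass,
                seed = stage_seed(config$seed, "validate"))
  matched <- val[c(m$treated, m$control), , drop = FALSE]
  smd_matched <- if (nrow(m) > 1) smd_table(matched, config$tau_predictors)
                 else smd
  readr::write_csv(smd_matched, art(config, "smd_matched.csv"))
  write_manifest(config, "validate", list(
    k = k, slope = calib$slope, intercept = calib$intercept,
    n_covered = calib$n_covered, n_bins = calib$n_bins,
    mean_abs_smd = mean(smd$smd, na.rm = TRUE),
    mean_abs_smd_matched = mean(smd_matched$smd, na.rm = TRUE),
    n_matched_pairs = nrow(m)))
  calib
}

stage_secondary <- function(config) {
  val <- read_cohort(need_artifact(config, "validation.csv", "filter"))
  cate <- readr::read_csv(need_artifact(config, "cate_validation.csv",
                                        "predict"), show_col_types = FALSE)
  grp <- assign_benefit_subgroups(cate, config$benefit_thresholds)
  sec <- secondary_outcome_models(val, grp, config$tau_predictors)
  readr::write_csv(sec, art(config, "secondary_outcomes.csv"))
  write_manifest(config, "secondary", list(n = nrow(val)))
  sec
}

stage_report <- function(config) {
  needed <- c("filter_log.csv", "selection.csv", "importance.csv",
              "cate_development.csv", "calibration.csv", "smd.csv",
              "secondary_outcomes.csv")
  missing <- needed[!file.exists(art(config, needed))]
  if (length(missing) > 0)
    abort(paste0("cannot assemble report; missing artifacts: ",
                 paste(missing, collapse = ", ")))
  cate <- readr::read_csv(art(config, "cate_development.csv"),
                          show_col_types = FALSE)
  grp <- assign_benefit_subgroups(cate, config$benefit_thresholds)
  prop <- tibble::tibble(subgroup = levels(grp),
                         n = as.integer(table(grp)),
                         percent = as.numeric(table(grp)) / length(grp) * 100)
  readr::write_csv(prop, art(config, "benefit_subgroups.csv"))
  calib <- readr::read_csv(art(config, "calibration.csv"),
                           show_col_types = FALSE)
  lines <- c(
    "Treatment selection model run report",
    "====================================",
    "",
    "Eligibility filter log:",
    readr::format_csv(readr::read_csv(art(config, "filter_log.csv"),
                                      show_col_types = FALSE)),
    "Predicted benefit subgroups (development cohort):",
    readr::format_csv(prop),
    sprintf("Mean predicted CATE: %.2f mmol/mol (SD %.2f)",
            mean(cate$cate_mean), sd(cate$cate_mean)),
    "",
    "Calibration (validation cohort): see calibration.csv",
    "Selection, importance, SMD and secondary-outcome tables: see CSVs.")
  writeLines(lines, art(config, "report.txt"))
  ok <- tryCatch({
    ggplot2::ggsave(art(config, "cate_distribution.png"),
                    autoplot.cate_summary(cate), width = 7, height = 4,
                    dpi = 150)
    cs <- structure(list(table = calib,
                         slope = NA_real_, intercept = NA_real_,
                         n_covered = sum(calib$covered),
                         n_bins = nrow(calib)),
                    class = "calibration_summary")
    cs$slope <- unname(coef(lm(ate_mean ~ predicted_cate, data = calib))[2])
    cs$intercept <- unname(coef(lm(ate_mean ~ predicted_cate,
                                   data = calib))[1])
    ggplot2::ggsave(art(config, "calibration.png"),
                    autoplot.calibration_summary(cs), width = 6, height = 5,
                    dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  write_manifest(config, "report", list(figures = ok))
  invisible(prop)
}

#' Run the full treatment selection pipeline
#'
#' Executes the enabled stages in order -- cohort simulation, eligibility
#' filtering and stratified splitting, propensity estimation, the sparse
#' selection fit, variable selection, the final parsimonious fit with CATE
#' prediction and importance, decile calibration validation with matching
#' balance, secondary outcomes, and the run report -- persisting every
#' stage's artifacts with a manifest under `config$out_dir`. A stage failure
#' halts the run with the stage named; completed artifacts remain on disk.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  results <- list()
  for (stage in config$stages) {
    results[[stage]] <- tryCatch(
      run_stage(config, stage),
      error = function(e) abort(paste0("pipeline halted at stage `", stage,
                                       "`: ", conditionMessage(e))))
  }
  invisible(results)
}
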