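#' Parameter-recovery and calibration study on a synthetic cohort
#'
#' Runs the full treatment selection analysis end to end against the
#' generator's oracle: simulate a cohort, apply eligibility and complete-case
#' filters, fit the propensity forest, fit the sparse selection model, select
#' variables, refit the parsimonious final model, and evaluate (i) the
#' Pearson correlation between posterior-mean predicted CATE and the true
#' CATE on the development cohort, and (ii) decile calibration of predicted
#' CATE against covariate-adjusted subgroup ATEs on an independently
#' generated probe cohort from the same generator (the probe is larger than
#' the development cohort so the subgroup ATEs are estimated precisely;
#' predicted-CATE self-calibration is an on-average property, so per-cohort
#' slopes fluctuate around 1 even for a perfectly calibrated model).
#'
#' @param seed Integer seed driving every stage.
#' @param n_dev Development cohort size after filtering (default 2000).
#' @param n_probe Raw size of the independent probe cohort (default 8000).
#' @param generator A [generator_config()]; its `n` and `seed` are
#'   overridden.
#' @param m_mu,m_tau Forest sizes (desk-scale defaults 50 and 20).
#' @param k Number of predicted-CATE bins (default 10).
#' @return A list: `corr`, calibration `slope` and `intercept`, `covered` of
#'   `n_bins`, `cate_sd`, the `selection` table, the development and probe
#'   sizes, and the per-bin calibration `table`.
#' @export
recovery_run <- function(seed, n_dev = 2000, n_probe = 8000,
                         generator = generator_config(), m_mu = 50,
                         m_tau = 20, k = 10) {
  gen <- generator
  gen$n <- ceiling(n_dev * 1.7)  # eligibility + complete-case attrition
  gen$seed <- stage_seed(seed, "recovery-dev")
  preds <- union(mu_predictor_set(), full_predictor_set())
  dev <- complete_cases(apply_eligibility(generate_cohort(gen))$cohort, preds)
  dev <- dev[seq_len(min(n_dev, nrow(dev))), , drop = FALSE]
  gen$n <- n_probe
  gen$seed <- stage_seed(seed, "recovery-probe")
  probe <- complete_cases(apply_eligibility(generate_cohort(gen))$cohort, preds)

  pf <- fit_propensity(dev, config = propensity_config(
    m = 100, n_iter = 600, n_burn = 300, cv_folds = 0,
    seed = stage_seed(seed, "recovery-ps")))
  sel_fit <- fit_bcf(dev, pihat = pf$pihat, config = bcf_config(
    m_mu = m_mu, m_tau = m_tau, n_iter = 3000, n_burn = 1500,
    sparsity = TRUE, seed = stage_seed(seed, "recovery-selfit")))
  sel <- select_variables(sel_fit)
  mu_sel <- union(setdiff(sel$variable[sel$forest == "prognostic" & sel$selected],
                          "pihat"), "outcome_month")
  tau_sel <- sel$variable[sel$forest == "effect" & sel$selected]
  if (length(tau_sel) == 0) tau_sel <- full_predictor_set()
  pihat_in <- "pihat" %in% sel$variable[sel$forest == "prognostic" & sel$selected]

  fit <- fit_bcf(dev, mu_sel, tau_sel,
                 pihat = if (pihat_in) pf$pihat else NULL,
                 config = bcf_config(
                   m_mu = m_mu, m_tau = m_tau, n_iter = 5000, n_burn = 2500,
                   n_thin = 5, n_chains = 4, include_pihat_in_mu = pihat_in,
                   seed = stage_seed(seed, "recovery-final")))
  cate_dev <- predict_cate(fit)
  np <- probe
  np$pihat <- predict(pf, probe)
  cate_probe <- predict_cate(fit, newdata = np)

  bins <- decile_bins(cate_probe, k = k)
  pred_by_bin <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bins, cate = cate_probe$cate_mean),
                    .data$bin),
    predicted_cate = mean(.data$cate), .groups = "drop")
  ates <- dplyr::bind_rows(lapply(sort(unique(bins)), function(b)
    subgroup_ate_regression(probe, bins == b, subgroup = b)))
  ates$bin <- ates$subgroup
  cal <- calibration_summary(pred_by_bin, ates)

  fem <- dev$sex == "Female"
  list(corr = cor(cate_dev$cate_mean, dev$true_cate),
       slope = cal$slope, intercept = cal$intercept,
       covered = cal$n_covered, n_bins = cal$n_bins,
       cate_sd = sd(cate_dev$cate_mean),
       cate_mean = mean(cate_dev$cate_mean),
       true_sd = sd(dev$true_cate),
       pct_sglt2i_gt3 = mean(cate_dev$cate_mean < -3) * 100,
       pct_glp1ra_gt3 = mean(cate_dev$cate_mean > 3) * 100,
       sex_contrast = mean(cate_dev$cate_mean[fem]) -
         mean(cate_dev$cate_mean[!fem]),
       selection = sel, n_dev = nrow(dev), n_probe = nrow(probe),
       table = cal$table)
}
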