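#' Configuration of the Bayesian causal forest sampler
#'
#' The outcome model is `y = mu(x_mu) + tau(x_tau) * z + Normal(0, sigma)`,
#' with `z = 1` coding GLP1-RA. `mu` is a prognostic ensemble of `m_mu` trees
#' under the standard depth prior `p(split | depth d) = eta (1 + d)^(-beta)`
#' with `eta = 0.95, beta = 2`; `tau` is a deliberately shallower and smaller
#' treatment-effect ensemble (`eta = 0.25, beta = 3`) whose leaf scale gets a
#' half-normal hyperprior, shrinking the effect surface toward homogeneity.
#' The noise variance carries the usual scaled-inverse-chi-squared prior with
#' `nu` degrees of freedom and scale calibrated so the prior puts probability
#' `q` below the marginal outcome SD. With `sparsity = TRUE` each forest's
#' split-variable probability vector gets a Dirichlet prior with total
#' concentration `conc` and is updated conjugately from the split counts,
#' optionally with a discrete-grid hyperprior update on the concentration.
#'
#' @param m_mu,m_tau Prognostic / treatment-effect forest sizes (200, 50).
#' @param eta_mu,beta_mu,eta_tau,beta_tau Depth-prior parameters per forest.
#' @param k_mu Prognostic leaf-scale constant: on the min-max scaled outcome
#'   the leaf prior SD is `0.5 / (k_mu * sqrt(m_mu))`.
#' @param tau_scale_init Initial treatment-effect leaf SD on the scaled
#'   outcome (default `0.5 / (2 * sqrt(m_tau))`).
#' @param update_tau_scale Update the effect leaf scale under its half-normal
#'   hyperprior (default TRUE).
#' @param tau_hn_scale Half-normal hyperprior scale for the effect leaf SD;
#'   default `sd(y_scaled) / sqrt(m_tau)`, i.e. two prior SDs span twice the
#'   marginal outcome SD for the total effect surface.
#' @param nu,q Noise-variance prior degrees of freedom and calibration
#'   quantile (3, 0.9).
#' @param sparsity Dirichlet sparsity prior on split-variable probabilities.
#' @param conc Dirichlet total concentration (default 1, a sparse prior that
#'   concentrates splitting probability on the variables the likelihood
#'   favours; set to the number of encoded columns for a flat
#'   Dirichlet(1, ..., 1)).
#' @param conc_update Discrete-grid hyperprior update of the concentration.
#' @param include_pihat_in_mu Include the estimated propensity score as an
#'   extra prognostic predictor (default TRUE).
#' @param n_iter,n_burn,n_thin MCMC length, burn-in and thinning
#'   (2000, 1000, 1).
#' @param n_chains Number of independent chains; retained draws are pooled
#'   (chain `c` uses seed `seed + c - 1`).
#' @param max_depth_mu,max_depth_tau Optional depth caps (-1 = none; 0 forces
#'   stumps, used for conjugate checks).
#' @param min_leaf Minimum training rows per leaf (5).
#' @param p_grow,p_prune,p_change Structure-proposal mix (0.4, 0.4, 0.2).
#' @param max_cuts Maximum candidate cutpoints per predictor (100).
#' @param save_trees Keep sampled tree ensembles for out-of-sample prediction.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   retained draws.
#' @return An object of class `bcf_config`.
#' @export
bcf_config <- function(m_mu = 200, m_tau = 50,
                       eta_mu = 0.95, beta_mu = 2,
                       eta_tau = 0.25, beta_tau = 3,
                       k_mu = 2, tau_scale_init = NULL,
                       update_tau_scale = TRUE, tau_hn_scale = NULL,
                       nu = 3, q = 0.9,
                       sparsity = FALSE, conc = 1, conc_update = FALSE,
                       include_pihat_in_mu = TRUE,
                       n_iter = 2000, n_burn = 1000, n_thin = 1, n_chains = 1,
                       max_depth_mu = -1, max_depth_tau = -1, min_leaf = 5,
                       p_grow = 0.4, p_prune = 0.4, p_change = 0.2,
                       max_cuts = 100, save_trees = TRUE, seed = 1L) {
  assert_that(eta_mu > 0 && eta_mu < 1 && eta_tau > 0 && eta_tau < 1 &&
                beta_mu >= 0 && beta_tau >= 0,
              "depth prior requires eta in (0,1) and beta >= 0")
  assert_that(m_mu >= 1 && m_tau >= 1, "forest sizes must be >= 1")
  assert_that(n_burn < n_iter, "`n_burn` must be smaller than `n_iter`")
  structure(as.list(environment()), class = "bcf_config")
}

#' Configuration of the probit propensity forest
#'
#' @param m Number of trees (100).
#' @param eta,beta Depth-prior parameters (0.95, 2).
#' @param k Leaf-scale constant: leaf prior SD is `3 / (k * sqrt(m))` on the
#'   probit latent scale.
#' @param sparsity,conc Dirichlet sparsity prior settings.
#' @param n_iter,n_burn,n_thin MCMC settings (1000, 500, 1).
#' @param cv_folds Folds for the cross-validated discrimination diagnostic
#'   (default 5; 0 skips it and reports in-sample discrimination, which is
#'   optimistic for a flexible model).
#' @param min_leaf,max_cuts,save_trees,seed As in [bcf_config()].
#' @return An object of class `propensity_config`.
#' @export
propensity_config <- function(m = 100, eta = 0.95, beta = 2, k = 2,
                              sparsity = FALSE, conc = 1,
                              n_iter = 1000, n_burn = 500, n_thin = 1,
                              cv_folds = 5, min_leaf = 5, max_cuts = 100,
                              save_trees = TRUE, seed = 1L) {
  assert_that(n_burn < n_iter, "`n_burn` must be smaller than `n_iter`")
  structure(as.list(environment()), class = "propensity_config")
}

rank_auc <- function(score, label) {
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the probit tree-ensemble propensity model
#'
#' Estimates per-individual propensity scores, the posterior mean probability
#' of receiving GLP1-RA given covariates, with a probit tree ensemble fitted
#' by latent-variable (truncated normal) augmentation. The forest prior keeps
#' fitted probabilities away from 0 and 1 even under perfect separation.
#'
#' @param cohort Cohort tibble with complete predictor data and a binary
#'   `drugclass` column (0 = SGLT2i, 1 = GLP1-RA).
#' @param predictors Character vector of predictor columns (default
#'   [full_predictor_set()]).
#' @param config A [propensity_config()].
#' @return An object of class `propensity_fit` with elements `pihat` (strictly
#'   inside (0,1)), `auc` (cross-validated discrimination when
#'   `config$cv_folds > 0`, otherwise in-sample), `auc_insample`, split-count
#'   draws and the sampled forests for out-of-sample prediction.
#' @export
fit_propensity <- function(cohort, predictors = full_predictor_set(),
                           config = propensity_config()) {
  z <- cohort$drugclass
  assert_that(all(z %in% c(0, 1)), "`drugclass` must be 0/1")
  if (length(unique(z)) < 2) abort("both treatment arms must be present")
  enc <- make_encoder(cohort, predictors)
  X <- encode_matrix(cohort, enc)
  if (anyNA(X)) abort("propensity predictors contain missing values; apply complete_cases() first")
  cuts <- cutpoint_list(X, config$max_cuts)
  set.seed(config$seed)
  res <- pbart_mcmc_cpp(X, as.integer(z), cuts, config$m, config$eta,
                        config$beta, 3 / (config$k * sqrt(config$m)),
                        config$sparsity, config$conc %||% ncol(X), config$n_iter,
                        config$n_burn, config$n_thin, config$min_leaf,
                        0.4, 0.4, 0.2, config$save_trees)
  pihat <- pmin(pmax(res$pihat, 1e-6), 1 - 1e-6)
  colnames(res$counts) <- colnames(X)
  colnames(res$s) <- colnames(X)

  # cross-validated discrimination: out-of-fold posterior-mean probabilities
  auc_cv <- NA_real_
  folds <- config$cv_folds %||% 0
  if (folds > 1) {
    set.seed(config$seed + 999L)
    fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
    oof <- numeric(nrow(X))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(z[tr])) < 2) next
      set.seed(config$seed + f)
      rf <- pbart_mcmc_cpp(X[tr, , drop = FALSE], as.integer(z[tr]),
                           cutpoint_list(X[tr, , drop = FALSE], config$max_cuts),
                           config$m, config$eta, config$beta,
                           3 / (config$k * sqrt(config$m)), config$sparsity,
                           config$conc %||% ncol(X), config$n_iter,
                           config$n_burn, config$n_thin, config$min_leaf,
                           0.4, 0.4, 0.2, TRUE)
      ftrees <- rf$trees
      pr <- rowMeans(pnorm(forest_predict_cpp(ftrees, X[!tr, , drop = FALSE])))
      oof[!tr] <- pr
    }
    auc_cv <- rank_auc(oof, z)
  }

  structure(list(pihat = pihat,
                 auc = if (is.na(auc_cv)) rank_auc(pihat, z) else auc_cv,
                 auc_insample = rank_auc(pihat, z),
                 split_counts = res$counts, split_probs = res$s,
                 trees = res$trees, accept = res$accept, encoder = enc,
                 source_var = attr(X, "source_var"), config = config,
                 n = nrow(cohort)),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Probit tree-ensemble propensity fit\n")
  cat(sprintf("  n = %d, trees = %d, retained draws = %d\n", x$n,
              x$config$m, nrow(x$split_counts)))
  cat(sprintf("  discrimination AUC = %.3f (in-sample %.3f)\n", x$auc,
              x$auc_insample))
  cat(sprintf("  pihat range: [%.3f, %.3f]\n", min(x$pihat), max(x$pihat)))
  invisible(x)
}

#' Predict propensity scores for new individuals
#'
#' @param object A `propensity_fit`.
#' @param newdata Data frame with the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of posterior-mean propensity scores.
#' @export
predict.propensity_fit <- function(object, newdata, ...) {
  if (length(object$trees) == 0)
    abort("fit was run with save_trees = FALSE; cannot predict on new data")
  X <- encode_matrix(newdata, object$encoder)
  f <- forest_predict_cpp(object$trees, X)
  pmin(pmax(rowMeans(pnorm(f)), 1e-6), 1 - 1e-6)
}

#' Fit the Bayesian causal forest outcome model
#'
#' Fits the two-ensemble model
#' `HbA1c_outcome = mu(x_mu) + tau(x_tau) * z + Normal(0, sigma)` by
#' backfitting MCMC: each tree in turn receives a grow/prune/change structure
#' proposal evaluated on its partial residual, accepted by Metropolis-Hastings
#' with the conjugate normal leaf prior integrated out, after which leaf
#' values are drawn from their conjugate posteriors; the noise SD is updated
#' from its conjugate scaled-inverse-chi-squared full conditional, and (with
#' sparsity on) each forest's split-variable probability vector from its
#' conjugate Dirichlet given the current split counts. The treatment-effect
#' ensemble enters the likelihood only through treated (GLP1-RA) rows.
#'
#' @param cohort Cohort tibble with `outcome_hba1c`, `drugclass` and complete
#'   predictor columns.
#' @param mu_predictors Prognostic-surface predictors (default
#'   [mu_predictor_set()]).
#' @param tau_predictors Treatment-effect-surface predictors (default
#'   [full_predictor_set()]).
#' @param pihat Estimated propensity scores, required when
#'   `config$include_pihat_in_mu` is TRUE (the default, following the causal
#'   forest construction this model extends).
#' @param config A [bcf_config()].
#' @return An object of class `bcf_fit` holding retained draws of the
#'   per-individual prognostic value `mu`, treatment effect `tau` (model
#'   scale: the GLP1-RA effect on HbA1c) and noise SD, per-forest
#'   split-count and split-probability draws, mean leaf-depth draws,
#'   acceptance counters and the sampled ensembles for prediction.
#' @export
fit_bcf <- function(cohort, mu_predictors = mu_predictor_set(),
                    tau_predictors = full_predictor_set(), pihat = NULL,
                    config = bcf_config()) {
  z <- cohort$drugclass
  assert_that(all(z %in% c(0, 1)), "`drugclass` must be 0/1 (non-binary treatment)")
  if (length(unique(z)) < 2) abort("both treatment arms must be present")
  y <- cohort$outcome_hba1c
  if (anyNA(y)) abort("outcome contains missing values")

  enc_mu <- make_encoder(cohort, mu_predictors)
  enc_tau <- make_encoder(cohort, tau_predictors)
  Xmu <- encode_matrix(cohort, enc_mu)
  Xtau <- encode_matrix(cohort, enc_tau)
  src_mu <- attr(Xmu, "source_var")
  src_tau <- attr(Xtau, "source_var")
  if (config$include_pihat_in_mu) {
    if (is.null(pihat)) abort("`pihat` is required when include_pihat_in_mu = TRUE")
    Xmu <- cbind(Xmu, pihat = pihat)
  }
  if (anyNA(Xmu) || anyNA(Xtau))
    abort("predictors contain missing values; apply complete_cases() first")

  # min-max scale the outcome so the standard leaf-scale defaults apply
  ctr <- (min(y) + max(y)) / 2
  rng <- max(y) - min(y)
  if (rng == 0) rng <- 1
  ys <- (y - ctr) / rng
  sighat <- sd(ys)
  lambda <- stats::qchisq(1 - config$q, config$nu) * sighat^2 / config$nu
  sigma_mu_leaf <- 0.5 / (config$k_mu * sqrt(config$m_mu))
  tau_scale_init <- config$tau_scale_init %||% (0.5 / (2 * sqrt(config$m_tau)))
  tau_hn <- config$tau_hn_scale %||% (sighat / sqrt(config$m_tau))

  cuts_mu <- cutpoint_list(Xmu, config$max_cuts)
  cuts_tau <- cutpoint_list(Xtau[z == 1, , drop = FALSE], config$max_cuts)

  n_chains <- config$n_chains %||% 1
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- bcf_mcmc_cpp(
      Xmu, Xtau, ys, as.integer(z), cuts_mu, cuts_tau,
      config$m_mu, config$m_tau, config$eta_mu, config$beta_mu,
      config$eta_tau, config$beta_tau, sigma_mu_leaf,
      tau_scale_init, config$update_tau_scale, tau_hn,
      config$nu, lambda, sighat, config$sparsity,
      config$conc %||% ncol(Xmu), config$conc %||% ncol(Xtau),
      config$conc_update, config$n_iter,
      config$n_burn, config$n_thin, config$max_depth_mu,
      config$max_depth_tau, config$min_leaf, config$p_grow,
      config$p_prune, config$p_change, config$save_trees)
  }
  res <- chains[[1]]
  if (n_chains > 1) {
    res$mu <- do.call(rbind, lapply(chains, `[[`, "mu"))
    res$tau <- do.call(rbind, lapply(chains, `[[`, "tau"))
    res$sigma <- do.call(c, lapply(chains, `[[`, "sigma"))
    res$tau_leaf_scale <- do.call(c, lapply(chains, `[[`, "tau_leaf_scale"))
    res$counts_mu <- do.call(rbind, lapply(chains, `[[`, "counts_mu"))
    res$counts_tau <- do.call(rbind, lapply(chains, `[[`, "counts_tau"))
    res$s_mu <- do.call(rbind, lapply(chains, `[[`, "s_mu"))
    res$s_tau <- do.call(rbind, lapply(chains, `[[`, "s_tau"))
    res$depth_mu <- do.call(c, lapply(chains, `[[`, "depth_mu"))
    res$depth_tau <- do.call(c, lapply(chains, `[[`, "depth_tau"))
    res$trees_mu <- do.call(c, lapply(chains, `[[`, "trees_mu"))
    res$trees_tau <- do.call(c, lapply(chains, `[[`, "trees_tau"))
    res$accept_mu <- Reduce(`+`, lapply(chains, `[[`, "accept_mu"))
    res$accept_tau <- Reduce(`+`, lapply(chains, `[[`, "accept_tau"))
    res$bookkeeping_max_abs_err <-
      max(vapply(chains, `[[`, numeric(1), "bookkeeping_max_abs_err"))
  }

  colnames(res$counts_mu) <- colnames(Xmu)
  colnames(res$counts_tau) <- colnames(Xtau)
  colnames(res$s_mu) <- colnames(Xmu)
  colnames(res$s_tau) <- colnames(Xtau)
  if (config$include_pihat_in_mu) src_mu <- c(src_mu, "pihat")

  structure(list(
    mu = t(res$mu) * rng + ctr,            # n x draws, outcome scale
    tau = t(res$tau) * rng,                # n x draws, GLP1-RA effect
    sigma = res$sigma * rng,
    tau_leaf_scale = res$tau_leaf_scale * rng,
    split_counts = list(mu = res$counts_mu, tau = res$counts_tau),
    split_probs = list(mu = res$s_mu, tau = res$s_tau),
    depth = list(mu = res$depth_mu, tau = res$depth_tau),
    trees = list(mu = res$trees_mu, tau = res$trees_tau),
    accept = list(mu = res$accept_mu, tau = res$accept_tau),
    bookkeeping_max_abs_err = res$bookkeeping_max_abs_err,
    scale = list(center = ctr, range = rng),
    encoder_mu = enc_mu, encoder_tau = enc_tau,
    source_var = list(mu = src_mu, tau = src_tau),
    sparsity = config$sparsity, config = config,
    n = nrow(cohort), z = z, y = y, id = cohort$id %||% seq_len(nrow(cohort))),
    class = "bcf_fit")
}

#' @export
print.bcf_fit <- function(x, ...) {
  D <- ncol(x$mu)
  cat("Bayesian causal forest fit\n")
  cat(sprintf("  n = %d (GLP1-RA %d, SGLT2i %d), retained draws = %d\n",
              x$n, sum(x$z == 1), sum(x$z == 0), D))
  cat(sprintf("  forests: %d prognostic + %d treatment-effect trees%s\n",
              x$config$m_mu, x$config$m_tau,
              if (x$sparsity) " (Dirichlet sparsity on)" else ""))
  cat(sprintf("  posterior mean noise SD = %.2f mmol/mol\n", mean(x$sigma)))
  cate <- -rowMeans(x$tau)
  cat(sprintf("  display CATE (SGLT2i - GLP1-RA): mean %.2f, SD %.2f mmol/mol\n",
              mean(cate), sd(cate)))
  invisible(x)
}

#' Draw from the Dirichlet full conditional of split-variable probabilities
#'
#' Given per-variable split counts and a total concentration `a`, draws from
#' `Dirichlet(a / p + counts)`; this is the conjugate update used for the
#' sparsity prior inside the sampler, exposed for testing and reuse.
#'
#' @param counts Non-negative integer vector of per-variable split counts.
#' @param concentration Total Dirichlet concentration (default 1).
#' @return Probability vector summing to 1.
#' @export
update_split_probs <- function(counts, concentration = 1) {
  p <- length(counts)
  if (p == 0) abort("`counts` must have positive length")
  assert_that(all(counts >= 0), "`counts` must be non-negative")
  g <- stats::rgamma(p, shape = concentration / p + counts, rate = 1)
  if (sum(g) <= 0) return(rep(1 / p, p))
  g / sum(g)
}

#' Summarise predicted conditional average treatment effects
#'
#' Evaluates the per-draw treatment-effect surface (at the training rows, or
#' at `newdata`) and reports, on the display scale, the posterior mean and
#' equal-tailed 95% credible interval of the predicted HbA1c difference:
#' predicted outcome on SGLT2i minus predicted outcome on GLP1-RA, so
#' negative values favour SGLT2i. Predicted outcomes under each arm are also
#' reported. For `newdata`, the outcome-month covariate (a prognostic-only
#' predictor) is fixed at 12 months, and `newdata` must carry a `pihat`
#' column when the model was fitted with the propensity score in the
#' prognostic surface.
#'
#' @param fit A [fit_bcf()] result (with `save_trees = TRUE` for `newdata`).
#' @param newdata Optional data frame of new individuals.
#' @return A `cate_summary` tibble with columns `id`, `cate_mean`,
#'   `cate_lower`, `cate_upper`, `pred_sglt2i`, `pred_glp1ra`; the per-draw
#'   display-CATE matrix is attached as attribute `"draws"`.
#' @export
predict_cate <- function(fit, newdata = NULL) {
  if (is.null(newdata)) {
    tau <- fit$tau
    mu <- fit$mu
    id <- fit$id
  } else {
    if (length(fit$trees$tau) == 0)
      abort("fit was run with save_trees = FALSE; cannot predict on new data")
    nd <- newdata
    if ("outcome_month" %in% fit$encoder_mu$vars) nd$outcome_month <- 12
    Xtau <- encode_matrix(nd, fit$encoder_tau)
    Xmu <- encode_matrix(nd, fit$encoder_mu)
    if (fit$config$include_pihat_in_mu) {
      if (!"pihat" %in% names(nd))
        abort("newdata must contain a `pihat` column for this model")
      Xmu <- cbind(Xmu, pihat = nd$pihat)
    }
    tau <- forest_predict_cpp(fit$trees$tau, Xtau) * fit$scale$range
    mu <- forest_predict_cpp(fit$trees$mu, Xmu) * fit$scale$range +
      fit$scale$center
    id <- newdata$id %||% seq_len(nrow(newdata))
  }
  disp <- -tau
  out <- tibble::tibble(
    id = id,
    cate_mean = rowMeans(disp),
    cate_lower = apply(disp, 1, quantile, 0.025, names = FALSE),
    cate_upper = apply(disp, 1, quantile, 0.975, names = FALSE),
    pred_sglt2i = rowMeans(mu),
    pred_glp1ra = rowMeans(mu + tau))
  attr(out, "draws") <- disp
  class(out) <- c("cate_summary", class(out))
  out
}

#' Propensity-score sensitivity refit
#'
#' Refits the model twice with identical settings, once without and once with
#' the propensity score in the prognostic predictor set, and reports the
#' concordance of the two sets of per-individual CATE predictions (Pearson
#' correlation and mean absolute difference). Checks that conclusions do not
#' hinge on whether the propensity score is modelled explicitly.
#'
#' @param cohort Cohort tibble.
#' @param mu_predictors,tau_predictors Selected predictor sets.
#' @param pihat Estimated propensity scores.
#' @param config A [bcf_config()]; `include_pihat_in_mu` is overridden per arm
#'   of the comparison.
#' @return An object of class `pihat_sensitivity`: per-individual CATE means
#'   from both fits, their correlation and mean absolute difference, and
#'   distribution summaries.
#' @export
refit_with_pihat_sensitivity <- function(cohort,
                                         mu_predictors = mu_predictor_set(),
                                         tau_predictors = full_predictor_set(),
                                         pihat, config = bcf_config()) {
  cfg_a <- config; cfg_a$include_pihat_in_mu <- FALSE
  cfg_b <- config; cfg_b$include_pihat_in_mu <- TRUE
  fit_a <- fit_bcf(cohort, mu_predictors, tau_predictors, pihat = NULL, cfg_a)
  fit_b <- fit_bcf(cohort, mu_predictors, tau_predictors, pihat = pihat, cfg_b)
  ca <- predict_cate(fit_a)
  cb <- predict_cate(fit_b)
  smry <- function(x) c(mean = mean(x), sd = sd(x),
                        quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  structure(list(
    cate = tibble::tibble(id = ca$id, cate_without_pihat = ca$cate_mean,
                          cate_with_pihat = cb$cate_mean),
    correlation = cor(ca$cate_mean, cb$cate_mean),
    mean_abs_difference = mean(abs(ca$cate_mean - cb$cate_mean)),
    summary_without_pihat = smry(ca$cate_mean),
    summary_with_pihat = smry(cb$cate_mean),
    fit_without_pihat = fit_a, fit_with_pihat = fit_b),
    class = "pihat_sensitivity")
}

#' @export
print.pihat_sensitivity <- function(x, ...) {
  cat("Propensity-score sensitivity refit\n")
  cat(sprintf("  correlation of CATE predictions: %.3f\n", x$correlation))
  cat(sprintf("  mean absolute difference: %.3f mmol/mol\n",
              x$mean_abs_difference))
  invisible(x)
}
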