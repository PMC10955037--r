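test_that("split-probability draws follow the conjugate Dirichlet", {
  set.seed(1)
  s <- update_split_probs(c(3, 0, 1), concentration = 1)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_error(update_split_probs(integer(0)), "positive length")
  expect_error(update_split_probs(c(-1, 2)), "non-negative")

  # heavy counts dominate a small concentration
  s_dom <- replicate(20, update_split_probs(c(100, 0, 0, 0), 0.1))
  expect_true(all(s_dom[1, ] > 0.9))

  # repeated draws match the analytic Dirichlet mean within 3 SEs
  counts <- c(5, 2, 0, 1)
  a <- 2
  draws <- replicate(10000, update_split_probs(counts, a))
  alpha <- a / 4 + counts
  expected <- alpha / sum(alpha)
  v <- expected * (1 - expected) / (sum(alpha) + 1)
  for (j in 1:4)
    expect_lt(abs(mean(draws[j, ]) - expected[j]), 3 * sqrt(v[j] / 10000))
})

test_that("depth-0 stump forests reproduce the conjugate normal posterior", {
  set.seed(3)
  n <- 500
  z <- rbinom(n, 1, 0.4)
  y <- 70 - 5 * z + rnorm(n, 0, 10)
  coh <- tibble::tibble(id = 1:n, x1 = rnorm(n), drugclass = z,
                        outcome_hba1c = y)
  cfg <- bcf_config(m_mu = 1, m_tau = 1, max_depth_mu = 0, max_depth_tau = 0,
                    k_mu = 0.005, tau_scale_init = 50,
                    update_tau_scale = FALSE, include_pihat_in_mu = FALSE,
                    n_iter = 2000, n_burn = 500, seed = 5)
  fit <- fit_bcf(coh, mu_predictors = "x1", tau_predictors = "x1",
                 config = cfg)
  # flat-prior limit of the conjugate posterior: control mean and arm contrast
  mu_chain <- fit$mu[1, ]
  tau_chain <- fit$tau[1, ]
  expect_lt(abs(mean(mu_chain) - mean(y[z == 0])), 3 * mcse(mu_chain))
  expect_lt(abs(mean(tau_chain) - (mean(y[z == 1]) - mean(y[z == 0]))),
            3 * mcse(tau_chain))
  # every individual shares the stump values
  expect_equal(max(apply(fit$mu, 2, function(col) diff(range(col)))), 0)
})

test_that("backfitting bookkeeping and seed determinism hold exactly", {
  coh <- clean_cohort(400, seed = 12)
  fit1 <- fit_bcf(coh, config = fast_bcf(seed = 77))
  fit2 <- fit_bcf(coh, config = fast_bcf(seed = 77))
  expect_identical(fit1$mu, fit2$mu)
  expect_identical(fit1$tau, fit2$tau)
  expect_identical(fit1$sigma, fit2$sigma)
  expect_lt(fit1$bookkeeping_max_abs_err, 1e-8)

  fit3 <- fit_bcf(coh, config = fast_bcf(seed = 78))
  expect_false(identical(fit1$sigma, fit3$sigma))
})

test_that("the effect forest samples shallower trees than the prognostic forest", {
  coh <- clean_cohort(600, seed = 13)
  fit <- fit_bcf(coh, config = bcf_config(
    m_mu = 25, m_tau = 25, n_iter = 800, n_burn = 300,
    include_pihat_in_mu = FALSE, seed = 4))
  expect_gte(length(fit$depth$mu), 500)
  expect_lt(mean(fit$depth$tau), mean(fit$depth$mu))
})

test_that("fit_bcf validates its inputs", {
  coh <- clean_cohort(100, seed = 14)
  expect_error(bcf_config(n_iter = 100, n_burn = 100), "n_burn")
  bad <- coh
  bad$drugclass <- sample(0:2, 100, replace = TRUE)
  expect_error(fit_bcf(bad, config = fast_bcf()), "0/1")
  one_arm <- coh
  one_arm$drugclass <- 0
  expect_error(fit_bcf(one_arm, config = fast_bcf()), "both treatment arms")
  expect_error(fit_bcf(coh, config = bcf_config(include_pihat_in_mu = TRUE,
                                                m_mu = 10, m_tau = 5,
                                                n_iter = 100, n_burn = 50)),
               "pihat")
})

test_that("propensity scores stay honest without confounding and with it", {
  # assignment independent of covariates: no discrimination
  coh0 <- clean_cohort(1500, seed = 21,
                       assignment_coefs = c(intercept = -1.1))
  pf0 <- fit_propensity(coh0, config = fast_propensity(seed = 1, cv_folds = 5))
  expect_lte(pf0$auc, 0.55)          # cross-validated discrimination
  expect_gte(pf0$auc_insample, pf0$auc)
  expect_lt(abs(mean(pf0$pihat) - mean(coh0$drugclass)), 0.05)

  # assignment driven by BMI: fitted propensity monotone in binned BMI
  coh1 <- clean_cohort(1500, seed = 22,
                       assignment_coefs = c(intercept = -1, bmi = 1.5))
  pf1 <- fit_propensity(coh1, config = fast_propensity(seed = 1))
  bin <- cut(coh1$bmi, quantile(coh1$bmi, 0:5 / 5), include.lowest = TRUE)
  mono <- tapply(pf1$pihat, bin, mean)
  expect_true(all(diff(mono) > 0))

  # perfect separation: prior regularisation keeps pihat off the boundary
  sep <- coh1[1:200, ]
  sep$drugclass <- as.integer(sep$bmi > 35)
  pf2 <- fit_propensity(sep, config = fast_propensity(seed = 1, cv_folds = 5))
  expect_true(all(pf2$pihat > 0.001 & pf2$pihat < 0.999))
  expect_gt(pf2$auc, 0.9)

  expect_error(fit_propensity(dplyr::mutate(coh0, drugclass = 1)),
               "both treatment arms")
})

test_that("noise-free constant treatment effects are recovered individually", {
  coh <- clean_cohort(1000, seed = 9, noise_sd = 0,
                      effect_coefs = c(intercept = -5))
  fit <- fit_bcf(coh, config = bcf_config(
    m_mu = 30, m_tau = 10, n_iter = 1000, n_burn = 500,
    include_pihat_in_mu = FALSE, seed = 2))
  cate <- predict_cate(fit)
  expect_gte(mean(abs(cate$cate_mean - 5) <= 0.5), 0.95)
})

test_that("a pure-noise outcome keeps 0 inside the average-effect interval", {
  coh <- clean_cohort(1000, seed = 31, effect_coefs = c(intercept = 0),
                      assignment_coefs = c(intercept = -1.1))
  fit <- fit_bcf(coh, config = fast_bcf(seed = 3))
  avg <- colMeans(-fit$tau)
  ci <- quantile(avg, c(0.025, 0.975))
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("predict_cate is consistent with the stored draws and sign rules", {
  coh <- clean_cohort(500, seed = 41,
                      effect_coefs = c(intercept = 0, sex = -4.4),
                      noise_sd = 5)
  fit <- fit_bcf(coh, config = fast_bcf(seed = 6))
  cate <- predict_cate(fit)
  expect_equal(cate$cate_mean, -rowMeans(fit$tau))
  draws <- attr(cate, "draws")
  expect_equal(cate$cate_lower,
               apply(draws, 1, quantile, 0.025, names = FALSE))
  expect_equal(cate$cate_upper,
               apply(draws, 1, quantile, 0.975, names = FALSE))
  expect_true(all(cate$cate_lower <= cate$cate_mean &
                    cate$cate_mean <= cate$cate_upper))
  # display CATE equals predicted SGLT2i outcome minus predicted GLP1-RA outcome
  expect_equal(cate$cate_mean, cate$pred_sglt2i - cate$pred_glp1ra)

  # two rows identical except sex: women toward GLP1-RA under the sex effect
  nd <- coh[c(1, 1), ]
  nd$sex <- factor(c("Male", "Female"), levels = c("Male", "Female"))
  pc <- predict_cate(fit, newdata = nd)
  expect_gt(pc$cate_mean[2] - pc$cate_mean[1], 0)

  bad <- nd
  bad$ethnicity <- factor(c("Martian", "White"))
  expect_error(predict_cate(fit, newdata = bad), "Martian")
})

test_that("an uninformative propensity column barely moves predictions", {
  coh <- clean_cohort(600, seed = 51, noise_sd = 5)
  sens <- refit_with_pihat_sensitivity(
    coh, pihat = rep(0.5, 600),
    config = bcf_config(m_mu = 30, m_tau = 10, n_iter = 2000, n_burn = 1000,
                        n_chains = 2, seed = 8))
  expect_lte(sens$mean_abs_difference, 0.5)
  expect_gt(sens$correlation, 0.9)
  expect_named(sens$summary_without_pihat,
               c("mean", "sd", "2.5%", "25%", "50%", "75%", "97.5%"))
  expect_equal(nrow(sens$cate), 600)
})

test_that("pooled multi-chain fits stack retained draws", {
  coh <- clean_cohort(200, seed = 61)
  f1 <- fit_bcf(coh, config = fast_bcf(seed = 5))
  f2 <- fit_bcf(coh, config = fast_bcf(seed = 5, n_chains = 2))
  expect_equal(ncol(f2$mu), 2 * ncol(f1$mu))
  expect_equal(f2$mu[, seq_len(ncol(f1$mu))], f1$mu)
  expect_equal(length(f2$trees$tau), 2 * length(f1$trees$tau))
})
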