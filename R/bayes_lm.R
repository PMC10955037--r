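# Conjugate Bayesian linear regression: beta | sigma2 ~ N(0, sigma2 / lambda),
# p(sigma2) ~ 1/sigma2. Posterior beta | y is multivariate t with df = n,
# location (X'X + lambda I)^-1 X'y; as lambda -> 0 the posterior mean is the
# least-squares estimate, which pins the estimator contract for oracle tests.
bayes_lm <- function(X, y, prior_precision = 1e-6) {
  n <- length(y)
  p <- ncol(X)
  A <- crossprod(X) + diag(prior_precision, p)
  Ainv <- tryCatch(solve(A), error = function(e)
    abort("design is numerically singular; increase prior_precision"))
  m <- Ainv %*% crossprod(X, y)
  s_n <- max(sum(y^2) - drop(t(m) %*% A %*% m), 0)
  se <- sqrt(pmax(s_n / n * diag(Ainv), 0))
  list(coef = setNames(drop(m), colnames(X)),
       se = setNames(se, colnames(X)), df = n, s_n = s_n)
}

bayes_lm_interval <- function(fit, term, level = 0.95) {
  q <- qt(1 - (1 - level) / 2, fit$df)
  est <- fit$coef[term]
  c(mean = unname(est), lower = unname(est - q * fit$se[term]),
    upper = unname(est + q * fit$se[term]))
}
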