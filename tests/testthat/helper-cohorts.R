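# Generation helpers shared across the suite: fully observed cohorts (no
# missingness, so model fits need no filtering) and fast sampler settings.

clean_cohort <- function(n, seed, ...) {
  generate_cohort(generator_config(n = n, seed = seed, missing_rates = c(), ...))
}

fast_bcf <- function(...) {
  bcf_config(m_mu = 30, m_tau = 10, n_iter = 600, n_burn = 300,
             include_pihat_in_mu = FALSE, ...)
}

fast_propensity <- function(..., cv_folds = 0) {
  propensity_config(m = 50, n_iter = 400, n_burn = 200, cv_folds = cv_folds,
                    ...)
}

# ten exchangeable standard-normal candidate covariates; used for selection
# and importance studies where the clinical schema is irrelevant
generic_generator <- function(n, seed, effect_coefs, prognostic_coefs,
                              noise_sd = 10,
                              assignment_coefs = c(intercept = -0.5)) {
  xs <- setNames(lapply(1:10, function(i)
    list(type = "continuous", mean = 0, sd = 1, lower = -5, upper = 5)),
    paste0("x", 1:10))
  R <- diag(10)
  dimnames(R) <- list(names(xs), names(xs))
  generator_config(n = n, covariate_spec = xs, correlation = R,
                   assignment_coefs = assignment_coefs,
                   prognostic_coefs = prognostic_coefs,
                   effect_coefs = effect_coefs, noise_sd = noise_sd,
                   missing_rates = c(), seed = seed)
}

# independent oracle for truncated-normal moments via numeric integration
truncnorm_moments_oracle <- function(mean, sd, lower, upper) {
  z <- integrate(function(x) dnorm(x, mean, sd), lower, upper)$value
  m <- integrate(function(x) x * dnorm(x, mean, sd), lower, upper)$value / z
  v <- integrate(function(x) (x - m)^2 * dnorm(x, mean, sd), lower,
                 upper)$value / z
  list(mean = m, sd = sqrt(v))
}

# batch-means Monte-Carlo standard error for a chain of draws
mcse <- function(x, n_batches = 40) {
  b <- floor(length(x) / n_batches)
  m <- tapply(x[seq_len(b * n_batches)],
              rep(seq_len(n_batches), each = b), mean)
  sd(m) / sqrt(n_batches)
}
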