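expit <- function(x) 1 / (1 + exp(-x))

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# deterministic per-stage seed derived from a global seed and a stage name;
# kept below 2^31 so it is always a valid R integer seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 131 * h) %% 2147483647L)
}

# moments of a normal truncated to [a, b]; used to state what the copula
# margins actually deliver once physiological bounds are applied
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# quantile function of the truncated normal via inverse-cdf
qtruncnorm <- function(u, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}
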