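test_that("the restricted cubic spline matches its closed form", {
  B <- rcs_basis(c(-1, 0.5, 3), knots = c(0, 1, 2))
  expect_equal(unname(B[1, "nonlinear"]), 0)            # zero left of the first knot
  expect_equal(unname(B[3, "nonlinear"]), 3)            # (27 - 16 + 1) / 4
  B2 <- rcs_basis(c(2, 3, 4), knots = c(0, 1, 2))
  # exactly linear beyond the boundary knot
  expect_equal(unname(B2[3, "nonlinear"] - B2[2, "nonlinear"]),
               unname(B2[2, "nonlinear"] - B2[1, "nonlinear"]))
  expect_error(rcs_basis(c(1, 1, 1)), "distinct")
})

test_that("the spline is linear outside arbitrary knot triples", {
  set.seed(4)
  direct <- function(x, k) {
    pp3 <- function(u) pmax(u, 0)^3
    (pp3(x - k[1]) - pp3(x - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
       pp3(x - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
  }
  for (rep in 1:20) {
    k <- sort(rnorm(3, sd = 5))
    if (min(diff(k)) < 0.1) next
    x <- seq(k[1] - 3, k[3] + 3, length.out = 101)
    B <- rcs_basis(x, knots = k)
    expect_equal(B[, "nonlinear"], direct(x, k), tolerance = 1e-10)
    # second differences vanish where the whole 3-point stencil lies
    # outside the boundary knots
    stencil_out <- (x[1:99] <= k[1] & x[3:101] <= k[1]) |
      (x[1:99] >= k[3] & x[3:101] >= k[3])
    d2 <- diff(B[, "nonlinear"], differences = 2)
    expect_lt(max(abs(d2[stencil_out])), 1e-8)
  }
})

test_that("the adjusted subgroup ATE equals least squares in the diffuse limit", {
  set.seed(7)
  n <- 400
  coh <- tibble::tibble(
    id = 1:n, age = rnorm(n, 58, 10), drugclass = rbinom(n, 1, 0.5))
  coh$outcome_hba1c <- 70 - 5 * coh$drugclass + 0.2 * coh$age
  est <- subgroup_ate_regression(coh, covariates = "age")
  expect_equal(est$ate_mean, 5, tolerance = 1e-6)  # display: +5 toward GLP1-RA
  expect_true(est$estimable)

  one_arm <- dplyr::mutate(coh, drugclass = 1)
  expect_warning(na_est <- subgroup_ate_regression(one_arm,
                                                   covariates = "age"),
                 "single")
  expect_false(na_est$estimable)
})

test_that("adjustment removes confounding that the raw contrast shows", {
  set.seed(8)
  n <- 2000
  x <- rnorm(n)
  z <- rbinom(n, 1, plogis(1.5 * x))
  y <- 70 + 8 * x + rnorm(n, 0, 2)   # no treatment effect at all
  coh <- tibble::tibble(id = 1:n, x = x, drugclass = z, outcome_hba1c = y)
  raw <- mean(y[z == 0]) - mean(y[z == 1])
  expect_gt(abs(raw), 2)
  est <- subgroup_ate_regression(coh, covariates = "x")
  expect_true(est$ate_lower <= 0 && 0 <= est$ate_upper)
})

test_that("unadjusted null coverage of the subgroup ATE is near nominal", {
  set.seed(9)
  hits <- 0
  for (r in 1:50) {
    n <- 500
    coh <- tibble::tibble(id = 1:n, x = rnorm(n),
                          drugclass = rbinom(n, 1, 0.5),
                          outcome_hba1c = rnorm(n, 70, 10))
    est <- subgroup_ate_regression(coh, covariates = "x")
    hits <- hits + (est$ate_lower <= 0 && 0 <= est$ate_upper)
  }
  expect_gte(hits, 45)
})

test_that("greedy matching follows the caliper and hand-run pairing", {
  # identical scores, opposite arms: matched at distance 0
  m <- ps_match(c(0.4, 0.4), c(1, 0), seed = 1)
  expect_equal(m$treated, 1)
  expect_equal(m$control, 2)
  expect_equal(m$distance, 0)

  # distances beyond the caliper stay unmatched
  expect_warning(m2 <- ps_match(c(0.9, 0.1), c(1, 0),
                                caliper_sd_logit = 0.2, seed = 1),
                 "no valid")
  expect_equal(nrow(m2), 0)

  # six-row fixture with unambiguous nearest neighbours
  pihat <- c(0.30, 0.50, 0.70, 0.31, 0.52, 0.90)
  z <- c(1, 1, 1, 0, 0, 0)
  m3 <- ps_match(pihat, z, caliper_sd_logit = 0.5, seed = 3)
  m3 <- m3[order(m3$treated), ]
  expect_equal(m3$treated, c(1, 2))
  expect_equal(m3$control, c(4, 5))   # 0.70 has no control inside the caliper
})

test_that("matching on a confounded cohort improves covariate balance", {
  coh <- clean_cohort(2000, seed = 71)
  pf <- fit_propensity(coh, config = fast_propensity(seed = 1))
  confs <- c("bmi", "ndrugs_ever", "sex", "egfr", "hba1c_baseline", "age")
  before <- mean(smd_table(coh, confs)$smd)
  m <- ps_match(pf$pihat, coh$drugclass, seed = 2)
  matched <- coh[c(m$treated, m$control), ]
  after <- mean(smd_table(matched, confs)$smd)
  expect_lt(after, before)
})

test_that("standardised mean differences reproduce the published arithmetic", {
  expect_equal(round(smd_continuous(57.7, 11.2, 58.4, 10.8), 3), 0.064)
  expect_equal(round(smd_continuous(92.0, 19.7, 94.7, 15.5), 3), 0.152)
  expect_equal(round(smd_binary(13121 / 28081, 32905 / 84193), 3), 0.155)
  expect_equal(smd_continuous(5, 1, 5, 1), 0)

  coh <- tibble::tibble(drugclass = rep(c(1, 0), each = 50),
                        x = c(rnorm(50, 1), rnorm(50, 0)),
                        b = rep(c(1, 0), 50),
                        const = 1)
  expect_warning(tab <- smd_table(coh, c("x", "b", "const")), "undefined")
  x1 <- coh$x[coh$drugclass == 1]; x0 <- coh$x[coh$drugclass == 0]
  expect_equal(tab$smd[tab$variable == "x"],
               round(abs(mean(x1) - mean(x0)) /
                       sqrt((var(x1) + var(x0)) / 2), 3))
  expect_true(is.na(tab$smd[tab$variable == "const"]))
})

test_that("calibration summaries recover identity and null relationships", {
  pred <- tibble::tibble(bin = 1:5, predicted_cate = c(-4, -2, 0, 2, 4))
  ate <- tibble::tibble(bin = 1:5, ate_mean = c(-4, -2, 0, 2, 4),
                        ate_lower = c(-5, -3, -1, 1, 3),
                        ate_upper = c(-3, -1, 1, 3, 5),
                        subgroup = 1:5)
  cal <- calibration_summary(pred, ate)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$n_covered, 5)

  ate0 <- dplyr::mutate(ate, ate_mean = 0, ate_lower = -1, ate_upper = 1)
  expect_equal(calibration_summary(pred, ate0)$slope, 0, tolerance = 1e-10)

  degenerate <- dplyr::mutate(pred, predicted_cate = 1)
  expect_error(calibration_summary(degenerate, ate), "degenerate")
  expect_error(calibration_summary(pred[1, ], ate[1, ]), "at least 2")
})

test_that("estimator families agree on a well-specified cohort", {
  coh <- clean_cohort(2000, seed = 81, noise_sd = 10)
  pf <- fit_propensity(coh, config = fast_propensity(seed = 3))
  reg <- subgroup_ate_regression(coh)
  mat <- subgroup_ate_matched(coh, pihat = pf$pihat, seed = 4)
  adj <- subgroup_ate_matched(coh, pihat = pf$pihat, adjust = TRUE, seed = 4)
  expect_equal(adj$estimator, "matched+adjusted")
  # overlapping 95% intervals across the three estimators
  lo <- max(reg$ate_lower, mat$ate_lower, adj$ate_lower)
  hi <- min(reg$ate_upper, mat$ate_upper, adj$ate_upper)
  expect_lt(lo, hi)
})

test_that("secondary-outcome contrasts hit their generating values", {
  # noise-free weight model: contrast is exactly +2 kg (GLP1-RA - SGLT2i)
  coh <- clean_cohort(800, seed = 91,
                      weight_effects = list(sglt2i = -4, glp1ra = -2, sd = 0))
  grp <- factor(rep(c("A", "B"), 400))
  sec <- secondary_outcome_models(coh, grp, covariates = "age",
                                  outcomes = "weight_change")
  expect_equal(sec$contrast, rep(2, 2), tolerance = 1e-6)
  expect_true(all(sec$estimable))

  # equal-rate discontinuation: odds-ratio intervals cover 1
  set.seed(10)
  hits <- 0
  for (r in 1:10) {
    coh2 <- clean_cohort(600, seed = 200 + r,
                         discontinuation = list(rate = 0.15, benefit_coef = 0))
    g2 <- factor(rep("all", 600))
    s2 <- secondary_outcome_models(coh2, g2, covariates = "age",
                                   outcomes = "discontinuation")
    hits <- hits + (s2$lower <= 1 && 1 <= s2$upper)
  }
  expect_gte(hits, 9)

  # an empty subgroup-arm cell is flagged, not fatal
  coh3 <- clean_cohort(200, seed = 95)
  g3 <- factor(ifelse(coh3$drugclass == 1, "onlyglp", "mixed"))
  s3 <- secondary_outcome_models(coh3, g3, covariates = "age",
                                 outcomes = "weight_change")
  expect_false(s3$estimable[s3$subgroup == "onlyglp"])
})
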