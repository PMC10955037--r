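fake_fit <- function(probs_mu, probs_tau, src_mu = colnames(probs_mu),
                     src_tau = colnames(probs_tau)) {
  structure(list(split_probs = list(mu = probs_mu, tau = probs_tau),
                 split_counts = list(mu = probs_mu, tau = probs_tau),
                 source_var = list(mu = src_mu, tau = src_tau),
                 sparsity = TRUE),
            class = "bcf_fit")
}

test_that("selection keeps variables above the uniform benchmark, per forest", {
  pm <- matrix(rep(c(0.6, 0.3, 0.05, 0.05), each = 10), nrow = 10,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  sel <- select_variables(fake_fit(pm, pm))
  expect_equal(sel$selected[sel$forest == "effect"],
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unique(sel$threshold), 0.25)

  # raising the threshold never adds variables
  for (thr in c(0.1, 0.25, 0.5, 0.7)) {
    s <- suppressWarnings(select_variables(fake_fit(pm, pm), threshold = thr))
    if (thr > 0.1)
      expect_true(all(s$variable[s$selected] %in% prev$variable[prev$selected]))
    prev <- s
  }

  # perfectly uniform probabilities select nothing, with a warning
  unif <- matrix(0.25, nrow = 5, ncol = 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_warning(s0 <- select_variables(fake_fit(unif, unif)), "no variable")
  expect_false(any(s0$selected))
})

test_that("categorical indicator columns aggregate to their parent variable", {
  pm <- matrix(rep(c(0.2, 0.2, 0.25, 0.35), each = 5), nrow = 5,
               dimnames = list(NULL, c("eth=A", "eth=B", "x1", "x2")))
  sel <- select_variables(fake_fit(pm, pm, src_mu = c("eth", "eth", "x1", "x2"),
                                   src_tau = c("eth", "eth", "x1", "x2")))
  eff <- sel[sel$forest == "effect", ]
  expect_equal(eff$split_probability[eff$variable == "eth"], 0.4)
  # eth's benchmark is 2 columns of 4, x1's is 1 of 4
  expect_equal(eff$threshold[eff$variable == "eth"], 0.5)
  expect_equal(eff$threshold[eff$variable == "x1"], 0.25)
  expect_false(eff$selected[eff$variable == "eth"])
  expect_true(eff$selected[eff$variable == "x2"])
})

test_that("best linear projection recovers exact linear effect structure", {
  set.seed(2)
  n <- 5000
  cov <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  cate <- tibble::tibble(cate_mean = 2 * cov$x1)
  imp <- best_linear_projection(cate, cov)
  expect_gt(imp$relative_importance[imp$term == "x1"], 95)
  expect_equal(sum(imp$relative_importance), 100, tolerance = 1e-6)

  cate2 <- tibble::tibble(cate_mean = cov$x1 + cov$x2)
  imp2 <- best_linear_projection(cate2, cov)
  i1 <- imp2$relative_importance[imp2$term == "x1"]
  expect_lt(abs(i1 - 50), 3 * 100 / sqrt(n))

  # standardization inside the operation: rescaling leaves importance alone
  cov_resc <- dplyr::mutate(cov, x1 = x1 * 1000)
  imp3 <- best_linear_projection(cate2, cov_resc)
  expect_equal(imp3$relative_importance[imp3$term == "x1"], i1,
               tolerance = 1e-9)

  expect_warning(impc <- best_linear_projection(
    tibble::tibble(cate_mean = rep(1, n)), cov), "undefined")
  expect_equal(unique(impc$relative_importance), 100 / 3, tolerance = 1e-9)

  expect_warning(best_linear_projection(
    tibble::tibble(cate_mean = cov$x1),
    dplyr::mutate(cov, x4 = x1)), "collinear")
})

test_that("benefit subgroups follow the sign and threshold semantics", {
  cate <- tibble::tibble(cate_mean = c(-6, -4, -3, -0.5, 0, 2.9, 3, 4, 5.1))
  g <- assign_benefit_subgroups(cate)
  expect_equal(as.character(g),
               c("SGLT2i benefit >5", "SGLT2i benefit 3-5", "SGLT2i benefit 0-3",
                 "SGLT2i benefit 0-3", "SGLT2i benefit 0-3",
                 "GLP1-RA benefit 0-3", "GLP1-RA benefit 0-3",
                 "GLP1-RA benefit 3-5", "GLP1-RA benefit >5"))
  expect_false(anyNA(g))          # labels partition the cohort
  expect_equal(nlevels(g), 6)
  expect_error(assign_benefit_subgroups(cate, thresholds = c(5, 3)),
               "ascending")
})

test_that("rank bins are near-equal with stable tie-breaking", {
  cate <- tibble::tibble(cate_mean = rnorm(100))
  b <- decile_bins(cate, 10)
  expect_equal(as.numeric(table(b)), rep(10, 10))

  b2 <- decile_bins(tibble::tibble(cate_mean = rnorm(101)), 10)
  expect_lte(diff(range(table(b2))), 1)

  expect_warning(b3 <- decile_bins(tibble::tibble(cate_mean = rep(1, 50)), 5),
                 "equal")
  expect_lte(diff(range(table(b3))), 1)

  expect_error(decile_bins(tibble::tibble(cate_mean = rnorm(5)), 10),
               "at least")
})

test_that("IFCC to NGSP conversion reproduces the clinical anchors", {
  expect_equal(hba1c_units(53, digits = 1), 7.0)
  expect_equal(hba1c_units(86, digits = 1), 10.0)
  expect_equal(hba1c_units(0), 2.152)
  expect_error(hba1c_units(-1), "non-negative")
})
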