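test_that("an empty request yields an empty table with the full schema", {
  tab <- generate_cohort(generator_config(n = 0))
  expect_equal(nrow(tab), 0)
  expect_true(all(c("id", "age", "sex", "bmi", "drugclass", "outcome_hba1c",
                    "outcome_month", "true_cate") %in% names(tab)))
})

test_that("identical config and seed reproduce the cohort exactly", {
  a <- generate_cohort(generator_config(n = 500, seed = 42))
  b <- generate_cohort(generator_config(n = 500, seed = 42))
  d <- generate_cohort(generator_config(n = 500, seed = 43))
  expect_identical(a, b)
  expect_false(identical(a$outcome_hba1c, d$outcome_hba1c))
})

test_that("noise-free constant effect gives exact counterfactual differences", {
  cfg <- generator_config(n = 300, seed = 3, noise_sd = 0,
                          effect_coefs = c(intercept = -5),
                          missing_rates = c())
  coh <- generate_cohort(cfg)
  # outcome decomposes exactly into prognostic surface plus -5 per GLP1-RA row
  expect_equal(coh$outcome_hba1c, coh$true_mu - 5 * coh$drugclass,
               tolerance = 1e-12)
  expect_equal(coh$true_cate, rep(5, 300))
})

test_that("true_cate evaluates the display-sign effect surface", {
  coh <- clean_cohort(200, seed = 8)
  cfg0 <- generator_config(n = 200, effect_coefs = c(intercept = 0))
  expect_equal(true_cate(cfg0, coh), rep(0, 200))

  # reported sex effect: women 4.4 mmol/mol more responsive to GLP1-RA
  cfg_sex <- generator_config(n = 200, effect_coefs = c(intercept = 0, sex = -4.4))
  tc <- true_cate(cfg_sex, coh)
  expect_equal(tc[coh$sex == "Female"],
               rep(4.4, sum(coh$sex == "Female")))
  expect_equal(tc[coh$sex == "Male"], rep(0, sum(coh$sex == "Male")))

  # direct evaluation of an arbitrary linear form
  cfg_lin <- generator_config(
    n = 200, effect_coefs = c(intercept = 2, age = 1.5, sex = -3, bmi = 0.5))
  ten <- coh[1:10, ]
  by_hand <- -(2 + 1.5 * (ten$age - 58.2) / 10.9 +
                 -3 * (ten$sex == "Female") +
                 0.5 * (ten$bmi - 34.6) / 7.15)
  expect_equal(true_cate(cfg_lin, ten), by_hand, tolerance = 1e-12)

  expect_error(true_cate(generator_config(effect_coefs = c(nope = 1)), coh),
               "unknown covariate")
})

test_that("invalid distribution parameters fail naming the covariate", {
  spec <- default_covariate_spec()
  spec$ethnicity$probs <- c(0.5, 0.2, 0.2, 0.05, 0.04)  # sums to 0.99
  expect_error(generator_config(covariate_spec = spec), "ethnicity")
  spec <- default_covariate_spec()
  spec$bmi$sd <- -1
  expect_error(generator_config(covariate_spec = spec), "bmi")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(month_dist = list(min = 1, max = 15)),
               "month_dist")
})

test_that("continuous marginals match their truncated-normal targets", {
  coh <- clean_cohort(10000, seed = 101)
  spec <- default_covariate_spec()
  for (v in c("age", "hba1c_baseline", "bmi", "egfr", "hdl", "map")) {
    sp <- spec[[v]]
    tm <- truncnorm_moments_oracle(sp$mean, sp$sd, sp$lower, sp$upper)
    se <- tm$sd / sqrt(10000)
    expect_lt(abs(mean(coh[[v]]) - tm$mean), 3 * se)
    expect_lt(abs(sd(coh[[v]]) - tm$sd), 3 * tm$sd / sqrt(2 * 10000))
  }
})

test_that("outcome months stay inside the ascertainment window", {
  coh <- clean_cohort(2000, seed = 5)
  expect_true(all(coh$outcome_month >= 3 & coh$outcome_month <= 15))
  expect_true(all(coh$drugclass %in% c(0, 1)))
})

test_that("the confounding knob moves between-arm balance", {
  bal <- clean_cohort(10000, seed = 7,
                      assignment_coefs = c(intercept = -1.1))
  smd_bal <- smd_table(bal, c("bmi", "ndrugs_ever", "egfr", "sex"))
  expect_true(all(smd_bal$smd < 0.08))

  conf <- clean_cohort(10000, seed = 7)
  smd_conf <- smd_table(conf, c("bmi", "ndrugs_ever"))
  expect_true(all(smd_conf$smd >= 0.1))
})

test_that("default arm-specific BMI means match the published baseline table", {
  coh <- generate_cohort(generator_config(n = 50000, seed = 1))
  expect_lt(abs(mean(coh$bmi[coh$drugclass == 1], na.rm = TRUE) - 37.3), 0.3)
  expect_lt(abs(mean(coh$bmi[coh$drugclass == 0], na.rm = TRUE) - 33.7), 0.3)
})

test_that("cohorts and configs round-trip through their text formats", {
  coh <- generate_cohort(generator_config(n = 50, seed = 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, p)
  back <- read_cohort(p)
  expect_equal(nrow(back), 50)
  expect_equal(back$outcome_hba1c, coh$outcome_hba1c, tolerance = 1e-9)
  expect_equal(levels(back$sex), c("Male", "Female"))

  cfg <- generator_config(n = 123, seed = 9, noise_sd = 12)
  yp <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, yp)
  cfg2 <- read_generator_config(yp)
  expect_equal(cfg2$n, 123)
  expect_equal(cfg2$noise_sd, 12)
  expect_equal(cfg2$correlation, cfg$correlation)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})
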