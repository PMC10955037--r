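elig_fixture <- function() {
  base <- tibble::tibble(
    id = 1:10, same_day_multi = 0, days_since_prior_start = 400,
    first_line = 0, insulin = 0, esrd = 0, hba1c_baseline = 60,
    outcome_hba1c = 55, drugclass = rep(c(0, 1), 5))
  base$same_day_multi[1] <- 1
  base$days_since_prior_start[2] <- 30
  base$first_line[3] <- 1
  base$insulin[4] <- 1
  base$esrd[5] <- 1
  base$hba1c_baseline[6] <- NA
  base$hba1c_baseline[7] <- 52
  base$outcome_hba1c[8] <- NA
  base
}

test_that("the eligibility rules exclude one row each in the fixed order", {
  res <- apply_eligibility(elig_fixture())
  expect_equal(res$log$n_excluded, rep(1L, 8))
  expect_equal(res$log$n_remaining, 9:2)
  expect_equal(res$cohort$id, c(9L, 10L))
  # remaining counts reconcile with total excluded
  expect_equal(nrow(res$cohort), 10 - sum(res$log$n_excluded))
})

test_that("the baseline HbA1c threshold is strict", {
  d <- elig_fixture()[9:10, ]
  d$hba1c_baseline <- c(53, 52.999)
  res <- apply_eligibility(d)
  expect_equal(res$cohort$hba1c_baseline, 53)
  row <- res$log[res$log$rule == "baseline HbA1c < 53 mmol/mol", ]
  expect_equal(row$n_excluded, 1L)
})

test_that("eligibility filtering is idempotent", {
  once <- apply_eligibility(elig_fixture())$cohort
  twice <- apply_eligibility(once)$cohort
  expect_identical(once, twice)
})

test_that("a missing required column raises a schema error naming it", {
  d <- elig_fixture()
  d$insulin <- NULL
  expect_error(apply_eligibility(d), "insulin")
})

test_that("outcome ascertainment picks the closest in-window month", {
  m <- tibble::tibble(month = c(10, 13), hba1c = c(60, 58))
  got <- ascertain_outcome(m)
  expect_equal(got$month, 13)   # |13 - 12| < |10 - 12|
  expect_equal(got$hba1c, 58)

  expect_null(ascertain_outcome(tibble::tibble(month = c(2, 16),
                                               hba1c = c(60, 58))))
  expect_null(ascertain_outcome(tibble::tibble(month = numeric(),
                                               hba1c = numeric())))

  tie <- ascertain_outcome(tibble::tibble(month = c(11, 13), hba1c = c(1, 2)))
  expect_equal(tie$month, 11)   # equidistant ties go to the earlier month

  # window bounds are inclusive; list-of-pairs input also accepted
  got2 <- ascertain_outcome(list(c(3, 70), c(15, 71)))
  expect_equal(got2$month, 15)
})

test_that("the stratified split preserves arm proportions exactly", {
  coh <- tibble::tibble(id = 1:150, drugclass = rep(c(0, 1), c(100, 50)))
  sp <- split_dev_val(coh, 0.6, seed = 1)
  expect_equal(sum(sp$development$drugclass == 0), 60)
  expect_equal(sum(sp$development$drugclass == 1), 30)
  expect_equal(sort(c(sp$development$id, sp$validation$id)), 1:150)

  sp2 <- split_dev_val(coh, 0.6, seed = 2)
  expect_false(identical(sort(sp$development$id), sort(sp2$development$id)))
  expect_equal(nrow(sp2$development), nrow(sp$development))

  # round-half-up on a 5-row stratum
  small <- tibble::tibble(id = 1:5, drugclass = 0)
  expect_equal(nrow(split_dev_val(small, 0.6, seed = 1)$development), 3)

  expect_error(split_dev_val(coh[0, ], 0.6, seed = 1), "empty")
  expect_error(split_dev_val(coh, 1.2, seed = 1), "dev_fraction")
})

test_that("complete-case filtering matches brute-force enumeration", {
  coh <- clean_cohort(50, seed = 6)
  expect_identical(complete_cases(coh, c("age", "bmi")), coh)

  coh$bmi[3] <- NA
  expect_equal(nrow(complete_cases(coh, c("age", "bmi"))), 49)
  expect_equal(nrow(complete_cases(coh, "age")), 50)

  set.seed(1)
  for (v in c("age", "egfr", "hdl"))
    coh[[v]][sample(50, 8)] <- NA
  keep <- !is.na(coh$age) & !is.na(coh$egfr) & !is.na(coh$hdl) & !is.na(coh$bmi)
  expect_equal(nrow(complete_cases(coh, c("age", "egfr", "hdl", "bmi"))),
               sum(keep))

  expect_error(complete_cases(coh, "not_a_column"), "not_a_column")
})
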