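#' Default covariate marginals for the synthetic cohort
#'
#' Marginal distributions for the routine clinical features used by the
#' treatment selection model, chosen to match the published baseline table of
#' people with type 2 diabetes initiating SGLT2 inhibitors (SGLT2i) or GLP-1
#' receptor agonists (GLP1-RA) in UK primary care (weighted mixture of the two
#' arms, arm sizes 28,081 GLP1-RA and 84,193 SGLT2i). Continuous covariates
#' are truncated normals (bounds are physiological plausibility limits),
#' binary covariates are Bernoulli, and categorical/ordinal covariates carry
#' explicit level probabilities.
#'
#' @return A named list of per-covariate specifications. Continuous entries
#'   have `type`, `mean`, `sd`, `lower`, `upper`; binary entries have `type`,
#'   `p` (for `sex`, the probability of `"Female"`); categorical entries have
#'   `type`, `levels`, `probs`; ordinal entries are like categorical but with
#'   integer levels and are emitted as integers.
#' @export
default_covariate_spec <- function() {
  list(
    age           = list(type = "continuous", mean = 58.2, sd = 10.9, lower = 18,  upper = 95),
    dm_duration   = list(type = "continuous", mean = 9.4,  sd = 6.6,  lower = 0,   upper = 50),
    hba1c_baseline = list(type = "continuous", mean = 77.3, sd = 17.0, lower = 40, upper = 170),
    bmi           = list(type = "continuous", mean = 34.6, sd = 7.15, lower = 16,  upper = 70),
    egfr          = list(type = "continuous", mean = 94.0, sd = 16.7, lower = 15,  upper = 140),
    hdl           = list(type = "continuous", mean = 1.1,  sd = 0.3,  lower = 0.4, upper = 3),
    alt           = list(type = "continuous", mean = 34.6, sd = 20.3, lower = 5,   upper = 200),
    albumin       = list(type = "continuous", mean = 41.9, sd = 3.9,  lower = 25,  upper = 55),
    bilirubin     = list(type = "continuous", mean = 9.4,  sd = 4.9,  lower = 2,   upper = 40),
    tchol         = list(type = "continuous", mean = 4.33, sd = 1.1,  lower = 1.5, upper = 10),
    map           = list(type = "continuous", mean = 96.2, sd = 9.0,  lower = 60,  upper = 140),
    sex           = list(type = "binary", p = 0.410),
    heart_failure = list(type = "binary", p = 0.047),
    ihd           = list(type = "binary", p = 0.138),
    pad           = list(type = "binary", p = 0.049),
    neuropathy    = list(type = "binary", p = 0.250),
    retinopathy   = list(type = "binary", p = 0.376),
    ethnicity     = list(type = "categorical",
                         levels = c("White", "South Asian", "Black", "Other", "Mixed"),
                         probs = c(0.8007, 0.1306, 0.0440, 0.0144, 0.0103)),
    smoking       = list(type = "categorical",
                         levels = c("Active", "Ex-smoker", "Non-smoker"),
                         probs = c(0.1760, 0.5648, 0.2592)),
    imd_quintile  = list(type = "ordinal", levels = 1:5,
                         probs = c(0.1667, 0.1761, 0.1924, 0.2223, 0.2425)),
    ndrugs_ever   = list(type = "ordinal", levels = 2:5,
                         probs = c(0.1925, 0.2881, 0.3184, 0.2010)),
    ncurrtx       = list(type = "ordinal", levels = 0:4,
                         probs = c(0.0565, 0.3933, 0.4289, 0.1167, 0.0046))
  )
}

#' Default correlation structure for the continuous covariates
#'
#' Correlations for the Gaussian copula over the continuous covariates.
#' Values are modest clinically motivated associations (age with renal
#' function and diabetes duration, adiposity with lipids and liver enzymes).
#'
#' @return A symmetric positive-definite correlation matrix whose dimnames
#'   are the continuous covariates of [default_covariate_spec()].
#' @export
default_correlation <- function() {
  vars <- c("age", "dm_duration", "hba1c_baseline", "bmi", "egfr", "hdl",
            "alt", "albumin", "bilirubin", "tchol", "map")
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_cor <- function(R, a, b, r) {
    R[a, b] <- r
    R[b, a] <- r
    R
  }
  R <- set_cor(R, "age", "dm_duration", 0.35)
  R <- set_cor(R, "age", "egfr", -0.50)
  R <- set_cor(R, "age", "bmi", -0.10)
  R <- set_cor(R, "age", "tchol", -0.10)
  R <- set_cor(R, "dm_duration", "hba1c_baseline", 0.10)
  R <- set_cor(R, "bmi", "hdl", -0.20)
  R <- set_cor(R, "bmi", "alt", 0.20)
  R
}

# Assignment coefficients act on standardized covariates and set the logit of
# P(GLP1-RA). Calibrated once (large-n simulation) so the default generator
# reproduces the published arm-specific BMI means (37.3 GLP1-RA, 33.7 SGLT2i)
# and an overall GLP1-RA fraction near 0.25, then frozen.
default_assignment_coefs <- function() {
  c(intercept = -1.35, bmi = 0.55, ndrugs_ever = 0.40, sex = 0.28,
    egfr = -0.18, hba1c_baseline = 0.07, age = -0.05)
}

# Prognostic surface m(x) for achieved 12-month HbA1c (mmol/mol), on
# standardized covariates. The outcome-month term is a small linear drift so
# the outcome-month covariate is testably non-null.
default_prognostic_coefs <- function() {
  c(intercept = 64.5, hba1c_baseline = 9.9, age = -0.6, egfr = -0.4,
    ncurrtx = 1.2, dm_duration = 0.5, outcome_month = 0.9, neuropathy = 0.5)
}

# Treatment-effect surface t(x): the additive effect of GLP1-RA (vs SGLT2i)
# on achieved HbA1c, so negative coefficients mean GLP1-RA lowers HbA1c more.
# The displayed CATE is -t(x) (positive = GLP1-RA benefit). The sex
# coefficient reproduces the reported 4.4 mmol/mol greater GLP1-RA response
# in women; the remaining modifier magnitudes are free parameters chosen to
# give a display-CATE standard deviation near 3 mmol/mol.
default_effect_coefs <- function() {
  c(intercept = 1.70, sex = -4.4, hba1c_baseline = 1.6, egfr = 1.0,
    ncurrtx = 0.9, bmi = 0.6)
}

default_missing_rates <- function() {
  c(hba1c_baseline = 0.05, bmi = 0.03, egfr = 0.01, hdl = 0.03, alt = 0.04,
    albumin = 0.03, bilirubin = 0.03, tchol = 0.01, map = 0.01,
    smoking = 0.04, ethnicity = 0.02, outcome_hba1c = 0.10,
    baseline_weight = 0.05, outcome_weight = 0.15)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every distributional choice behind the synthetic cohort: covariate
#' marginals and their copula correlation, the true (confounded) treatment
#' assignment logit, the true prognostic surface `m(x)` and treatment-effect
#' surface `t(x)` in mmol/mol, the outcome noise, outcome-timing distribution
#' and per-field missingness. The object gives oracle access to the true
#' conditional average treatment effect (CATE) via [true_cate()].
#'
#' Coefficient vectors are named: `intercept`, covariate names (continuous and
#' ordinal covariates enter standardized by their nominal mean/SD; binary
#' covariates enter as 0/1 indicators, with `sex` coding `Female` as 1),
#' `"var=Level"` for a categorical level indicator, `"a:b"` for a product of
#' two standardized covariates and `"var^2"` for a squared standardized
#' covariate. `effect_coefs` parameterise `t(x)`, the additive GLP1-RA effect
#' on achieved HbA1c; the displayed CATE (positive = GLP1-RA benefit,
#' negative = SGLT2i benefit) is `-t(x)`.
#'
#' @param n Number of individuals (may be 0).
#' @param covariate_spec Per-covariate marginals, see [default_covariate_spec()].
#' @param correlation Correlation matrix for the continuous covariates'
#'   Gaussian copula, see [default_correlation()].
#' @param assignment_coefs Named coefficients of the treatment-assignment
#'   logit for P(GLP1-RA | x).
#' @param prognostic_coefs Named coefficients of `m(x)` in mmol/mol.
#' @param effect_coefs Named coefficients of `t(x)` in mmol/mol.
#' @param noise_sd Outcome noise SD in mmol/mol (default 15, the order of the
#'   observed 12-month response SDs).
#' @param month_dist Outcome-month distribution; a list with `min` and `max`
#'   (uniform on `[min, max]`, required to lie within `[3, 15]`).
#' @param missing_rates Named per-field missingness probabilities.
#' @param weight_effects 12-month weight change by arm (kg) and its noise SD.
#' @param discontinuation Baseline 6-month discontinuation rate and the
#'   log-odds decrease per mmol/mol of predicted benefit on the received drug.
#' @param seed Integer seed; identical config and seed give identical cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 10000,
                             covariate_spec = default_covariate_spec(),
                             correlation = default_correlation(),
                             assignment_coefs = default_assignment_coefs(),
                             prognostic_coefs = default_prognostic_coefs(),
                             effect_coefs = default_effect_coefs(),
                             noise_sd = 15,
                             month_dist = list(min = 3, max = 15),
                             missing_rates = default_missing_rates(),
                             weight_effects = list(sglt2i = -4, glp1ra = -2, sd = 5),
                             discontinuation = list(rate = 0.15, benefit_coef = 0.05),
                             seed = 1L) {
  cfg <- structure(
    list(n = n, covariate_spec = covariate_spec, correlation = correlation,
         assignment_coefs = assignment_coefs,
         prognostic_coefs = prognostic_coefs, effect_coefs = effect_coefs,
         noise_sd = noise_sd, month_dist = month_dist,
         missing_rates = missing_rates, weight_effects = weight_effects,
         discontinuation = discontinuation, seed = seed),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  assert_that(is.numeric(cfg$n) && length(cfg$n) == 1 && cfg$n >= 0,
              "`n` must be a single non-negative number")
  assert_that(cfg$noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(cfg$month_dist$min >= 3 && cfg$month_dist$max <= 15 &&
                cfg$month_dist$min <= cfg$month_dist$max,
              "`month_dist` must have support within [3, 15]")
  for (v in names(cfg$covariate_spec)) {
    sp <- cfg$covariate_spec[[v]]
    if (sp$type == "continuous") {
      if (!is.finite(sp$sd) || sp$sd <= 0 || sp$lower >= sp$upper)
        abort(paste0("invalid continuous distribution for covariate `", v, "`"))
    } else if (sp$type == "binary") {
      if (sp$p < 0 || sp$p > 1)
        abort(paste0("invalid Bernoulli probability for covariate `", v, "`"))
    } else if (sp$type %in% c("categorical", "ordinal")) {
      if (length(sp$levels) != length(sp$probs) || any(sp$probs < 0) ||
          abs(sum(sp$probs) - 1) > 1e-9)
        abort(paste0("level probabilities for covariate `", v,
                     "` must be non-negative and sum to 1"))
    } else {
      abort(paste0("unknown distribution type for covariate `", v, "`"))
    }
  }
  cont <- names(cfg$covariate_spec)[
    vapply(cfg$covariate_spec, function(s) s$type == "continuous", logical(1))]
  assert_that(identical(sort(rownames(cfg$correlation)), sort(cont)),
              "`correlation` dimnames must match the continuous covariates")
  ev <- eigen(cfg$correlation, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > 1e-10, "`correlation` must be positive definite")
  invisible(cfg)
}

# standardized value of a single coefficient term, given latent covariates
term_value <- function(term, data, cfg) {
  spec <- cfg$covariate_spec
  std1 <- function(v) {
    if (v == "outcome_month") {
      m <- (cfg$month_dist$min + cfg$month_dist$max) / 2
      s <- (cfg$month_dist$max - cfg$month_dist$min) / sqrt(12)
      return((data[["outcome_month"]] - m) / max(s, 1e-12))
    }
    if (!v %in% names(data))
      abort(paste0("unknown covariate `", v, "` in coefficients"))
    sp <- spec[[v]]
    if (is.null(sp)) abort(paste0("unknown covariate `", v, "` in coefficients"))
    x <- data[[v]]
    switch(sp$type,
      continuous = (x - sp$mean) / sp$sd,
      ordinal = {
        m <- sum(sp$levels * sp$probs)
        s <- sqrt(sum((sp$levels - m)^2 * sp$probs))
        (as.numeric(x) - m) / max(s, 1e-12)
      },
      binary = {
        if (v == "sex") as.numeric(x == "Female") else as.numeric(x)
      },
      abort(paste0("covariate `", v, "` is categorical; use `", v, "=Level`"))
    )
  }
  if (grepl("=", term, fixed = TRUE)) {
    parts <- strsplit(term, "=", fixed = TRUE)[[1]]
    v <- parts[1]; lev <- parts[2]
    if (!v %in% names(data))
      abort(paste0("unknown covariate `", v, "` in coefficients"))
    as.numeric(data[[v]] == lev)
  } else if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    std1(parts[1]) * std1(parts[2])
  } else if (grepl("^", term, fixed = TRUE)) {
    v <- sub("\\^2$", "", term)
    std1(v)^2
  } else {
    std1(term)
  }
}

linear_predictor <- function(coefs, data, cfg) {
  out <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (nm == "intercept") {
      out <- out + coefs[[nm]]
    } else {
      out <- out + coefs[[nm]] * term_value(nm, data, cfg)
    }
  }
  out
}

cohort_schema <- function(config) {
  c("id", names(config$covariate_spec), "same_day_multi",
    "days_since_prior_start", "first_line", "insulin", "esrd", "drugclass",
    "outcome_hba1c", "outcome_month", "baseline_weight", "outcome_weight",
    "discontinued_6m", "true_cate", "true_mu")
}

#' Generate a synthetic treatment cohort
#'
#' Draws a patient-level cohort with the statistical structure the treatment
#' selection analysis assumes: correlated covariates from a Gaussian copula
#' with truncation to physiological ranges, non-random (confounded) treatment
#' assignment `z ~ Bernoulli(expit(assignment logit))` with `z = 1` coding
#' GLP1-RA, an additive outcome
#' `HbA1c = m(x) + t(x) * z + Normal(0, noise_sd)`, variable outcome timing,
#' secondary outcomes (12-month weight change, 6-month discontinuation) and
#' study eligibility flags. Oracle columns `true_cate` (`-t(x)`, the
#' display-sign CATE: negative favours SGLT2i) and `true_mu` (`m(x)`) are
#' included for parameter-recovery testing; they are synthetic-data-only
#' columns with no real-data analogue.
#'
#' @param config A [generator_config()].
#' @return A `CohortTable` tibble, one row per treated individual.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n)
  spec <- config$covariate_spec

  cont <- names(spec)[vapply(spec, function(s) s$type == "continuous", logical(1))]
  R <- config$correlation[cont, cont]
  Z <- matrix(rnorm(n * length(cont)), nrow = n, ncol = length(cont)) %*% chol(R)
  U <- matrix(pnorm(Z), nrow = n, ncol = length(cont))
  dat <- tibble::tibble(id = seq_len(n))
  for (j in seq_along(cont)) {
    sp <- spec[[cont[j]]]
    dat[[cont[j]]] <- qtruncnorm(U[, j], sp$mean, sp$sd, sp$lower, sp$upper)
  }
  for (v in names(spec)) {
    sp <- spec[[v]]
    if (sp$type == "binary") {
      x <- rbinom(n, 1, sp$p)
      dat[[v]] <- if (v == "sex")
        factor(ifelse(x == 1, "Female", "Male"), levels = c("Male", "Female"))
      else as.integer(x)
    } else if (sp$type == "categorical") {
      dat[[v]] <- factor(sample(sp$levels, n, replace = TRUE, prob = sp$probs),
                         levels = sp$levels)
    } else if (sp$type == "ordinal") {
      dat[[v]] <- as.integer(sample(sp$levels, n, replace = TRUE, prob = sp$probs))
    }
  }

  dat$outcome_month <- runif(n, config$month_dist$min, config$month_dist$max)

  # confounded assignment: prescribing by indication
  lp_z <- linear_predictor(config$assignment_coefs, dat, config)
  dat$drugclass <- rbinom(n, 1, expit(lp_z))

  t_x <- linear_predictor(config$effect_coefs, dat, config)
  m_x <- linear_predictor(config$prognostic_coefs, dat, config)
  dat$true_cate <- -t_x
  dat$true_mu <- m_x
  dat$outcome_hba1c <- m_x + t_x * dat$drugclass + rnorm(n, 0, config$noise_sd)

  # weight: BMI times squared height, arm-specific 12-month change
  height <- pmin(pmax(rnorm(n, 1.69, 0.09), 1.40), 2.10)
  dat$baseline_weight <- if ("bmi" %in% names(dat)) dat$bmi * height^2
                         else rnorm(n, 95, 15)
  w_eff <- ifelse(dat$drugclass == 1, config$weight_effects$glp1ra,
                  config$weight_effects$sglt2i)
  dat$outcome_weight <- dat$baseline_weight + w_eff +
    rnorm(n, 0, config$weight_effects$sd)

  # discontinuation: lower when the received drug is the predicted-benefit drug
  benefit_received <- ifelse(dat$drugclass == 1, dat$true_cate, -dat$true_cate)
  lp_d <- qlogis(config$discontinuation$rate) -
    config$discontinuation$benefit_coef * benefit_received
  dat$discontinued_6m <- rbinom(n, 1, plogis(lp_d))

  # eligibility flag columns consumed by apply_eligibility()
  dat$same_day_multi <- rbinom(n, 1, 0.01)
  early <- rbinom(n, 1, 0.04) == 1
  dat$days_since_prior_start <- ifelse(early, runif(n, 0, 60.99),
                                       runif(n, 61, 1000))
  dat$first_line <- rbinom(n, 1, 0.03)
  dat$insulin <- rbinom(n, 1, 0.04)
  dat$esrd <- rbinom(n, 1, 0.003)

  # missingness applied after everything is generated (MCAR)
  for (v in names(config$missing_rates)) {
    if (!v %in% names(dat)) next
    miss <- runif(n) < config$missing_rates[[v]]
    dat[[v]][miss] <- NA
  }

  dat[, cohort_schema(config)]
}

#' Oracle conditional average treatment effect
#'
#' Evaluates the generating treatment-effect surface at supplied covariates
#' and returns it on the display scale used throughout: predicted HbA1c on
#' SGLT2i minus predicted HbA1c on GLP1-RA, i.e. `-t(x)`, so negative values
#' favour SGLT2i and positive values favour GLP1-RA.
#'
#' @param config A [generator_config()].
#' @param covariates A data frame with the covariates referenced by
#'   `config$effect_coefs`.
#' @return Numeric vector in mmol/mol, one value per row of `covariates`.
#' @export
true_cate <- function(config, covariates) {
  -linear_predictor(config$effect_coefs, covariates, config)
}

#' Read and write cohort tables and generator configurations
#'
#' Cohorts are stored as comma-separated text with a header row, UTF-8
#' encoded, missing values as empty fields. Generator configurations are
#' stored as YAML.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; the writers return `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dat <- readr::read_csv(path, na = "", show_col_types = FALSE)
  if ("sex" %in% names(dat))
    dat$sex <- factor(dat$sex, levels = c("Male", "Female"))
  if ("ethnicity" %in% names(dat)) dat$ethnicity <- factor(dat$ethnicity)
  if ("smoking" %in% names(dat)) dat$smoking <- factor(dat$smoking)
  dat
}

#' @rdname write_cohort
#' @param config A [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  lst <- unclass(config)
  lst$correlation <- list(vars = rownames(lst$correlation),
                          values = as.numeric(lst$correlation))
  for (nm in c("assignment_coefs", "prognostic_coefs", "effect_coefs",
               "missing_rates"))
    lst[[nm]] <- as.list(lst[[nm]])
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_generator_config <- function(path) {
  lst <- yaml::read_yaml(path)
  k <- length(lst$correlation$vars)
  R <- matrix(as.numeric(lst$correlation$values), k, k,
              dimnames = list(lst$correlation$vars, lst$correlation$vars))
  for (nm in c("assignment_coefs", "prognostic_coefs", "effect_coefs",
               "missing_rates"))
    lst[[nm]] <- unlist(lst[[nm]])
  lst$correlation <- R
  do.call(generator_config, lst[names(lst) %in% names(formals(generator_config))])
}
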