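#' Restricted cubic spline basis with three knots
#'
#' Expands a continuous covariate into a linear column plus one nonlinear
#' column using the truncated-power restricted cubic spline with knots
#' `t1 < t2 < t3`:
#' `B(x) = [(x-t1)+^3 - (x-t2)+^3 (t3-t1)/(t3-t2) + (x-t3)+^3 (t2-t1)/(t3-t2)] / (t3-t1)^2`.
#' The restriction makes the basis exactly linear beyond the boundary knots
#' and `B(x) = 0` for all `x <= t1`.
#'
#' @param x Numeric vector with at least 3 distinct values (unless `knots`
#'   are supplied).
#' @param knot_quantiles Quantiles at which to place the knots (default
#'   10/50/90 percentiles).
#' @param knots Optional explicit knots, overriding `knot_quantiles`.
#' @return A two-column matrix `(linear, nonlinear)` with the knots attached
#'   as attribute `"knots"`.
#' @export
rcs_basis <- function(x, knot_quantiles = c(0.10, 0.50, 0.90), knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(x[!is.na(x)])) < 3)
      abort("need at least 3 distinct values for a 3-knot spline")
    knots <- unname(quantile(x, knot_quantiles, na.rm = TRUE))
  }
  if (length(unique(knots)) < 3)
    abort("knots must be 3 distinct values")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  B <- (pp3(x - t1) - pp3(x - t2) * (t3 - t1) / (t3 - t2) +
          pp3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  out <- cbind(linear = x, nonlinear = B)
  attr(out, "knots") <- knots
  out
}

# adjustment design for the ATE regressions: treatment indicator plus the
# full covariate set, continuous covariates expanded to 3-knot restricted
# cubic splines, categoricals to indicator columns (first level dropped)
ate_design <- function(cohort, covariates) {
  cols <- list(`(Intercept)` = rep(1, nrow(cohort)),
               z = as.numeric(cohort$drugclass))
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- as.character(x)
      lev <- sort(unique(x))
      for (l in lev[-1]) cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
    } else {
      x <- as.numeric(x)
      ux <- unique(x)
      if (length(ux) > 5) {
        kn <- unname(quantile(x, c(0.10, 0.50, 0.90)))
        if (length(unique(kn)) == 3) {
          B <- rcs_basis(x, knots = kn)
          cols[[v]] <- B[, "linear"]
          cols[[paste0(v, "'")]] <- B[, "nonlinear"]
        } else cols[[v]] <- x
      } else cols[[v]] <- x
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Covariate-adjusted average treatment effect within a subgroup
#'
#' Estimates the subgroup average treatment effect (ATE) as the adjusted
#' difference in HbA1c outcome between arms: Bayesian linear regression of
#' the outcome on the treatment indicator and the full covariate set, with
#' continuous covariates as 3-knot restricted cubic splines, under a
#' conjugate prior whose diffuse limit is least squares. The ATE is reported
#' on the display sign (SGLT2i minus GLP1-RA, negative favours SGLT2i) with
#' an equal-tailed 95% credible interval.
#'
#' @param cohort Cohort tibble with `outcome_hba1c` and `drugclass`.
#' @param members Optional logical/integer vector selecting the subgroup
#'   (default: all rows).
#' @param covariates Adjustment covariates (default [full_predictor_set()]).
#' @param outcome Outcome column (default `"outcome_hba1c"`).
#' @param prior_precision Ridge prior precision (default `1e-6`, effectively
#'   diffuse).
#' @param subgroup Optional subgroup label carried into the result.
#' @return A one-row `ate_estimate` tibble: `subgroup`, `n_sglt2i`,
#'   `n_glp1ra`, `ate_mean`, `ate_lower`, `ate_upper`, `estimator`,
#'   `estimable`. A single-arm subgroup yields `estimable = FALSE` with a
#'   warning rather than an error.
#' @export
subgroup_ate_regression <- function(cohort, members = NULL,
                                    covariates = full_predictor_set(),
                                    outcome = "outcome_hba1c",
                                    prior_precision = 1e-6,
                                    subgroup = NA) {
  if (!is.null(members)) cohort <- cohort[members, , drop = FALSE]
  n0 <- sum(cohort$drugclass == 0)
  n1 <- sum(cohort$drugclass == 1)
  if (n0 == 0 || n1 == 0) {
    warn("subgroup has a single treatment arm; ATE not estimable")
    return(tibble::tibble(subgroup = subgroup, n_sglt2i = n0, n_glp1ra = n1,
                          ate_mean = NA_real_, ate_lower = NA_real_,
                          ate_upper = NA_real_, estimator = "regression",
                          estimable = FALSE))
  }
  X <- ate_design(cohort, covariates)
  fit <- bayes_lm(X, cohort[[outcome]], prior_precision)
  ci <- bayes_lm_interval(fit, "z")
  # display sign: z is the GLP1-RA effect on the outcome; negate
  out <- tibble::tibble(subgroup = subgroup, n_sglt2i = n0, n_glp1ra = n1,
                        ate_mean = -unname(ci["mean"]),
                        ate_lower = -unname(ci["upper"]),
                        ate_upper = -unname(ci["lower"]),
                        estimator = "regression", estimable = TRUE)
  class(out) <- c("ate_estimate", class(out))
  out
}

#' Propensity-matched average treatment effect within a subgroup
#'
#' Sensitivity estimators for the subgroup ATE: greedy 1:1 propensity-score
#' matching via [ps_match()] followed by either the plain matched-pairs mean
#' difference (`adjust = FALSE`, estimator tag `"matched"`) or the
#' covariate-adjusted regression of [subgroup_ate_regression()] restricted to
#' the matched set (`adjust = TRUE`, tag `"matched+adjusted"`). Reported on
#' the display sign (negative favours SGLT2i).
#'
#' @inheritParams subgroup_ate_regression
#' @param pihat Propensity scores for all rows of `cohort`.
#' @param adjust Add regression adjustment on the matched set.
#' @param caliper_sd_logit,seed Passed to [ps_match()].
#' @return A one-row `ate_estimate` tibble as in [subgroup_ate_regression()].
#' @export
subgroup_ate_matched <- function(cohort, members = NULL, pihat,
                                 covariates = full_predictor_set(),
                                 outcome = "outcome_hba1c", adjust = FALSE,
                                 caliper_sd_logit = 0.2, seed = 1L,
                                 prior_precision = 1e-6, subgroup = NA) {
  if (!is.null(members)) {
    cohort <- cohort[members, , drop = FALSE]
    pihat <- pihat[members]
  }
  tag <- if (adjust) "matched+adjusted" else "matched"
  pairs <- ps_match(pihat, cohort$drugclass, caliper_sd_logit, seed = seed)
  if (nrow(pairs) < 2) {
    warn("fewer than 2 matched pairs; matched ATE not estimable")
    return(tibble::tibble(subgroup = subgroup,
                          n_sglt2i = sum(cohort$drugclass == 0),
                          n_glp1ra = sum(cohort$drugclass == 1),
                          ate_mean = NA_real_, ate_lower = NA_real_,
                          ate_upper = NA_real_, estimator = tag,
                          estimable = FALSE))
  }
  if (adjust) {
    matched <- cohort[c(pairs$treated, pairs$control), , drop = FALSE]
    out <- subgroup_ate_regression(matched, covariates = covariates,
                                   outcome = outcome,
                                   prior_precision = prior_precision,
                                   subgroup = subgroup)
    out$estimator <- tag
    return(out)
  }
  # display sign: SGLT2i (control) minus GLP1-RA (treated) pair difference
  d <- cohort[[outcome]][pairs$control] - cohort[[outcome]][pairs$treated]
  se <- sd(d) / sqrt(length(d))
  q <- qt(0.975, length(d) - 1)
  out <- tibble::tibble(subgroup = subgroup,
                        n_sglt2i = nrow(pairs), n_glp1ra = nrow(pairs),
                        ate_mean = mean(d), ate_lower = mean(d) - q * se,
                        ate_upper = mean(d) + q * se, estimator = tag,
                        estimable = TRUE)
  class(out) <- c("ate_estimate", class(out))
  out
}

#' Greedy propensity-score matching
#'
#' 1:1 nearest-neighbour matching without replacement on the logit propensity
#' score, with a caliper of `caliper_sd_logit` standard deviations of the
#' logit. Treated (GLP1-RA) units are processed in a seed-determined random
#' order; each takes the nearest available control within the caliper, ties
#' resolving to the lower index. Deterministic given the seed and input
#' order.
#'
#' @param pihat Propensity scores strictly inside (0, 1).
#' @param treatment 0/1 treatment indicator (1 = treated arm to be matched).
#' @param caliper_sd_logit Caliper in SDs of the logit propensity (0.2).
#' @param ratio Controls matched per treated unit (default 1).
#' @param seed Integer seed for the processing order.
#' @return A tibble of matched pairs: `treated`, `control` (row indices into
#'   the input), `distance` (absolute logit difference). Empty, with a
#'   warning, when no pair fits the caliper.
#' @export
ps_match <- function(pihat, treatment, caliper_sd_logit = 0.2, ratio = 1,
                     seed = 1L) {
  assert_that(all(pihat > 0 & pihat < 1), "`pihat` must lie strictly in (0, 1)")
  lg <- qlogis(pihat)
  caliper <- caliper_sd_logit * sd(lg)
  treated <- which(treatment == 1)
  controls <- which(treatment == 0)
  set.seed(seed)
  order_t <- sample(treated)
  available <- rep(TRUE, length(controls))
  pairs <- vector("list", length(order_t) * ratio)
  k <- 0
  for (r in seq_len(ratio)) {
    for (t in order_t) {
      idx <- which(available)
      if (length(idx) == 0) break
      d <- abs(lg[controls[idx]] - lg[t])
      best <- idx[which.min(d)]  # which.min takes the first (lowest index) tie
      if (min(d) <= caliper) {
        k <- k + 1
        pairs[[k]] <- tibble::tibble(treated = t, control = controls[best],
                                     distance = min(d))
        available[best] <- FALSE
      }
    }
  }
  if (k == 0) {
    warn("no valid matched pairs within the caliper")
    return(tibble::tibble(treated = integer(), control = integer(),
                          distance = numeric()))
  }
  dplyr::bind_rows(pairs[seq_len(k)])
}

#' Standardised mean difference helpers
#'
#' `smd_continuous()` computes `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)` from
#' group means and SDs; `smd_binary()` is the same with variance
#' `p (1 - p)`. Values at or above 0.1 conventionally signal meaningful
#' between-arm imbalance.
#'
#' @param m1,s1,m2,s2 Group means and standard deviations.
#' @param p1,p2 Group proportions.
#' @return Absolute standardised mean difference.
#' @export
smd_continuous <- function(m1, s1, m2, s2) {
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (pooled == 0) return(NA_real_)
  abs(m1 - m2) / pooled
}

#' @rdname smd_continuous
#' @export
smd_binary <- function(p1, p2) {
  smd_continuous(p1, sqrt(p1 * (1 - p1)), p2, sqrt(p2 * (1 - p2)))
}

#' Between-arm covariate balance table
#'
#' Per-covariate group summaries and absolute standardised mean differences
#' between the GLP1-RA and SGLT2i arms. Continuous covariates use the pooled
#' SD of the two arms; binary covariates and categorical levels (expanded to
#' indicators) use the proportion variance `p(1-p)`. SMDs are reported to 3
#' decimal places; zero pooled variance yields `NA` with a warning.
#'
#' @param cohort Cohort tibble with a `drugclass` column; both arms present.
#' @param covariates Covariate columns to tabulate.
#' @return An `smd_table` tibble: `variable`, `type`, `mean_glp1ra`,
#'   `sd_glp1ra`, `mean_sglt2i`, `sd_sglt2i`, `smd`.
#' @export
smd_table <- function(cohort, covariates = full_predictor_set()) {
  assert_that(length(unique(cohort$drugclass)) == 2,
              "both treatment arms must be present")
  g1 <- cohort$drugclass == 1  # GLP1-RA
  rows <- list()
  add_cont <- function(name, x) {
    m1 <- mean(x[g1], na.rm = TRUE); s1 <- sd(x[g1], na.rm = TRUE)
    m0 <- mean(x[!g1], na.rm = TRUE); s0 <- sd(x[!g1], na.rm = TRUE)
    tibble::tibble(variable = name, type = "continuous", mean_glp1ra = m1,
                   sd_glp1ra = s1, mean_sglt2i = m0, sd_sglt2i = s0,
                   smd = round(smd_continuous(m1, s1, m0, s0), 3))
  }
  add_bin <- function(name, x) {
    p1 <- mean(x[g1], na.rm = TRUE)
    p0 <- mean(x[!g1], na.rm = TRUE)
    tibble::tibble(variable = name, type = "binary", mean_glp1ra = p1,
                   sd_glp1ra = sqrt(p1 * (1 - p1)), mean_sglt2i = p0,
                   sd_sglt2i = sqrt(p0 * (1 - p0)),
                   smd = round(smd_binary(p1, p0), 3))
  }
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- as.character(x)
      for (l in sort(unique(x[!is.na(x)])))
        rows[[paste0(v, "=", l)]] <- add_bin(paste0(v, "=", l),
                                             as.numeric(x == l))
    } else if (all(x %in% c(0, 1, NA))) {
      rows[[v]] <- add_bin(v, as.numeric(x))
    } else {
      rows[[v]] <- add_cont(v, as.numeric(x))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (any(is.na(out$smd)))
    warn(paste0("SMD undefined (zero pooled variance) for: ",
                paste(out$variable[is.na(out$smd)], collapse = ", ")))
  class(out) <- c("smd_table", class(out))
  out
}

#' Calibration of subgroup ATEs against predicted CATEs
#'
#' The validation framework's calibration surface: for subgroups (deciles or
#' quintiles of predicted CATE), regresses the covariate-adjusted subgroup
#' ATE on the subgroup's mean predicted CATE by inverse-variance-weighted
#' least squares. A well-calibrated model gives slope 1 and intercept 0, with
#' most subgroup ATE credible intervals covering the subgroup's mean
#' predicted CATE.
#'
#' @param predicted_by_bin Tibble with columns `bin` and `predicted_cate`
#'   (mean predicted display CATE per subgroup).
#' @param ate_by_bin Tibble of [subgroup_ate_regression()] rows with a `bin`
#'   column (or `subgroup` used as bin).
#' @return A `calibration_summary` object: the joined per-bin table, the
#'   weighted `slope` and `intercept`, and `n_covered` of `n_bins`.
#' @export
calibration_summary <- function(predicted_by_bin, ate_by_bin) {
  if (!"bin" %in% names(ate_by_bin)) ate_by_bin$bin <- ate_by_bin$subgroup
  tab <- dplyr::inner_join(predicted_by_bin, ate_by_bin, by = "bin")
  tab <- tab[!is.na(tab$ate_mean), , drop = FALSE]
  assert_that(nrow(tab) >= 2, "need at least 2 estimable bins")
  if (length(unique(tab$predicted_cate)) < 2)
    abort("predicted CATE is constant across bins; calibration is degenerate")
  se <- (tab$ate_upper - tab$ate_lower) / (2 * qnorm(0.975))
  wgt <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, nrow(tab))
  fit <- stats::lm(ate_mean ~ predicted_cate, data = tab, weights = wgt)
  tab$covered <- tab$ate_lower <= tab$predicted_cate &
    tab$predicted_cate <= tab$ate_upper
  structure(list(table = tibble::as_tibble(tab),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_covered = sum(tab$covered), n_bins = nrow(tab)),
            class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat("Subgroup ATE vs predicted CATE calibration\n")
  cat(sprintf("  slope = %.3f, intercept = %.3f\n", x$slope, x$intercept))
  cat(sprintf("  credible-interval coverage: %d of %d bins\n",
              x$n_covered, x$n_bins))
  invisible(x)
}

#' Secondary-outcome models with treatment-by-subgroup interactions
#'
#' Estimates per-subgroup arm contrasts for the short-term secondary
#' outcomes: 12-month weight change (linear model with a treatment-by-benefit
#' subgroup interaction, adjusted for baseline weight and the full covariate
#' set) and treatment discontinuation within 6 months (the logistic
#' analogue, reporting odds ratios). Estimation follows the same conjugate /
#' maximum-likelihood-limit contract as [subgroup_ate_regression()].
#'
#' @param cohort Cohort tibble with `outcome_weight`, `baseline_weight` and
#'   `discontinued_6m`.
#' @param subgroups Factor of benefit subgroup labels, one per row (e.g. from
#'   [assign_benefit_subgroups()]).
#' @param covariates Adjustment covariates (default [full_predictor_set()]).
#' @param outcomes Which secondary outcomes to fit.
#' @param prior_precision Ridge prior precision for the weight model.
#' @return Tibble with one row per outcome and subgroup: `outcome`,
#'   `subgroup`, `n_sglt2i`, `n_glp1ra`, `contrast` (weight change: GLP1-RA
#'   minus SGLT2i in kg; discontinuation: odds ratio GLP1-RA vs SGLT2i),
#'   `lower`, `upper`, `estimable`. Empty subgroup-arm cells are flagged
#'   not-estimable rather than failing.
#' @export
secondary_outcome_models <- function(cohort, subgroups,
                                     covariates = full_predictor_set(),
                                     outcomes = c("weight_change",
                                                  "discontinuation"),
                                     prior_precision = 1e-6) {
  g <- droplevels(factor(subgroups))
  z <- as.numeric(cohort$drugclass)
  levs <- levels(g)
  cells <- table(g, factor(z, levels = c(0, 1)))
  adj <- ate_design(cohort, covariates)
  adj <- adj[, setdiff(colnames(adj), c("(Intercept)", "z")), drop = FALSE]
  gmat <- sapply(levs, function(l) as.numeric(g == l))
  colnames(gmat) <- paste0("g:", levs)
  imat <- gmat * z
  colnames(imat) <- paste0("z:", levs)
  rows <- list()
  for (oc in outcomes) {
    if (oc == "weight_change") {
      y <- cohort$outcome_weight - cohort$baseline_weight
      X <- cbind(gmat, imat, baseline_weight = cohort$baseline_weight, adj)
      ok <- stats::complete.cases(cbind(y, X))
      fit <- bayes_lm(X[ok, , drop = FALSE], y[ok], prior_precision)
      for (l in levs) {
        est <- if (all(cells[l, ] > 0)) bayes_lm_interval(fit, paste0("z:", l))
               else c(mean = NA, lower = NA, upper = NA)
        rows[[paste(oc, l)]] <- tibble::tibble(
          outcome = oc, subgroup = l, n_sglt2i = cells[l, "0"],
          n_glp1ra = cells[l, "1"], contrast = unname(est["mean"]),
          lower = unname(est["lower"]), upper = unname(est["upper"]),
          estimable = all(cells[l, ] > 0))
      }
    } else if (oc == "discontinuation") {
      y <- cohort$discontinued_6m
      X <- cbind(gmat, imat, adj)
      ok <- stats::complete.cases(cbind(y, X))
      fit <- suppressWarnings(
        stats::glm.fit(X[ok, , drop = FALSE], y[ok], family = binomial()))
      cf <- coef(fit)
      # Wald normal approximation around the ML fit
      Xok <- X[ok, , drop = FALSE]
      p <- fit$fitted.values
      W <- p * (1 - p)
      V <- tryCatch(solve(crossprod(Xok * sqrt(W))), error = function(e) NULL)
      for (l in levs) {
        term <- paste0("z:", l)
        ok_cell <- all(cells[l, ] > 0) && !is.null(V) && !is.na(cf[term])
        if (ok_cell) {
          se <- sqrt(V[term, term])
          est <- exp(c(cf[term], cf[term] - 1.96 * se, cf[term] + 1.96 * se))
        } else est <- c(NA, NA, NA)
        rows[[paste(oc, l)]] <- tibble::tibble(
          outcome = oc, subgroup = l, n_sglt2i = cells[l, "0"],
          n_glp1ra = cells[l, "1"], contrast = est[1], lower = est[2],
          upper = est[3], estimable = ok_cell)
      }
    }
  }
  dplyr::bind_rows(rows)
}
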