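#' Variable selection from splitting probabilities
#'
#' Summarises, separately for the prognostic and treatment-effect forests,
#' the posterior mean probability that a tree split uses each candidate
#' variable (split-probability draws when the sparsity prior is on, otherwise
#' normalised split-count draws), aggregated over the indicator columns of
#' categorical predictors. The default rule retains variables whose posterior
#' mean splitting probability exceeds the uniform benchmark `1/p`, the
#' probability each variable would receive if splits were assigned at random.
#' For a variable encoded as `k` of the forest's `P` columns (a `k`-level
#' categorical) the benchmark is `k / P`, which reduces to `1/p` when every
#' candidate contributes one column.
#'
#' @param fit A [fit_bcf()] result.
#' @param threshold Optional scalar threshold overriding the per-variable
#'   uniform benchmark.
#' @return A `selection_result` tibble: `forest`, `variable`,
#'   `split_probability`, `threshold`, `selected`.
#' @export
select_variables <- function(fit, threshold = NULL) {
  one_forest <- function(which) {
    draws <- if (fit$sparsity) fit$split_probs[[which]]
             else {
               cnt <- fit$split_counts[[which]]
               tot <- rowSums(cnt)
               pr <- cnt / ifelse(tot == 0, 1, tot)
               pr[tot == 0, ] <- 1 / ncol(cnt)  # no splits: uninformative
               pr
             }
    if (nrow(draws) == 0) abort("no retained draws in fit")
    src <- fit$source_var[[which]]
    pm <- colMeans(draws)
    agg <- tapply(pm, src, sum)
    vars <- unique(src)
    probs <- as.numeric(agg[vars])
    ncols <- as.numeric(table(src)[vars])
    thr <- if (is.null(threshold)) ncols / length(src)
           else rep(threshold, length(vars))
    tibble::tibble(forest = if (which == "mu") "prognostic" else "effect",
                   variable = vars, split_probability = probs,
                   threshold = thr, selected = probs > thr)
  }
  out <- dplyr::bind_rows(one_forest("mu"), one_forest("tau"))
  if (!any(out$selected))
    warn("no variable exceeds the selection threshold in either forest")
  class(out) <- c("selection_result", class(out))
  out
}

#' Variable importance by best linear projection
#'
#' Regresses the posterior-mean display CATE on standardized covariates by
#' least squares; the projection coefficients are in mmol/mol per SD
#' (indicator covariates per level change) and relative importance is
#' `|coefficient| / sum |coefficients| * 100`. Standardization happens inside
#' the operation, so rescaling a covariate does not change its relative
#' importance. Collinear columns are dropped with a warning.
#'
#' @param cate A [predict_cate()] summary (or any data frame with a
#'   `cate_mean` column).
#' @param covariates Data frame of covariates, same rows as `cate`.
#' @return An `importance_table` tibble: `term`, `coefficient`
#'   (mmol/mol per SD), `relative_importance` (%, sums to 100).
#' @export
best_linear_projection <- function(cate, covariates) {
  y <- cate$cate_mean
  assert_that(nrow(covariates) == length(y),
              "`covariates` must have one row per CATE estimate")
  enc <- make_encoder(covariates, names(covariates))
  X <- encode_matrix(covariates, enc)
  # reference-level coding: drop each categorical's first level so the
  # intercept absorbs it instead of tripping the collinearity check
  drop_ref <- vapply(enc$vars, function(v) {
    sp <- enc$columns[[v]]
    if (sp$type == "categorical") paste0(v, "=", sp$levels[1]) else NA_character_
  }, character(1))
  X <- X[, setdiff(colnames(X), drop_ref), drop = FALSE]
  if (nrow(unique(X)) < 2) abort("need at least 2 distinct covariate rows")
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (any(!keep))
    warn(paste0("constant column(s) dropped: ",
                paste(colnames(X)[!keep], collapse = ", ")))
  Xs <- scale(X[, keep, drop = FALSE])
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
  beta <- fit$coefficients[-1]
  dropped <- names(beta)[is.na(beta)]
  if (length(dropped) > 0) {
    warn(paste0("collinear column(s) dropped: ", paste(dropped, collapse = ", ")))
    beta <- beta[!is.na(beta)]
  }
  tot <- sum(abs(beta))
  if (tot < 1e-12) {
    warn("CATE is constant under projection; importance is undefined, reporting uniform")
    imp <- rep(100 / length(beta), length(beta))
    beta[] <- 0
  } else {
    imp <- abs(beta) / tot * 100
  }
  out <- tibble::tibble(term = names(beta), coefficient = as.numeric(beta),
                        relative_importance = imp)
  out <- dplyr::arrange(out, dplyr::desc(.data$relative_importance))
  class(out) <- c("importance_table", class(out))
  out
}

#' Clinically-thresholded benefit subgroups
#'
#' Bins individuals by predicted HbA1c benefit: the sign of the display CATE
#' gives the favoured drug (negative, including exactly zero, favours SGLT2i)
#' and the absolute value is binned by the thresholds, boundaries belonging
#' to the lower bin (|CATE| = 3 is "0-3").
#'
#' @param cate A [predict_cate()] summary (or data frame with `cate_mean`).
#' @param thresholds Positive ascending benefit thresholds in mmol/mol
#'   (default `c(3, 5)`).
#' @return Factor of subgroup labels, ordered from strongest SGLT2i benefit
#'   to strongest GLP1-RA benefit.
#' @export
assign_benefit_subgroups <- function(cate, thresholds = c(3, 5)) {
  assert_that(all(thresholds > 0) && !is.unsorted(thresholds, strictly = TRUE),
              "`thresholds` must be positive ascending")
  x <- cate$cate_mean
  edges <- c(0, thresholds, Inf)
  labs <- character(length(thresholds) + 1)
  for (k in seq_len(length(thresholds) + 1)) {
    labs[k] <- if (k <= length(thresholds)) {
      sprintf("%g-%g", edges[k], edges[k + 1])
    } else sprintf(">%g", edges[k])
  }
  drug <- ifelse(x > 0, "GLP1-RA", "SGLT2i")  # sign 0 goes to SGLT2i
  bin <- cut(abs(x), breaks = c(-Inf, thresholds, Inf), labels = labs,
             right = TRUE)
  lab <- paste0(drug, " benefit ", as.character(bin))
  lev <- c(paste0("SGLT2i benefit ", rev(labs)), paste0("GLP1-RA benefit ", labs))
  factor(lab, levels = lev)
}

#' Rank-based near-equal bins of predicted CATE
#'
#' Deciles (or k-tiles) of predicted CATE with near-equal bin sizes (within
#' one); ties are broken by stable input order.
#'
#' @param cate A [predict_cate()] summary (or data frame with `cate_mean`).
#' @param k Number of bins (default 10; use 5 for small cohorts).
#' @return Integer vector of bin indices in 1..k (1 = strongest SGLT2i
#'   benefit).
#' @export
decile_bins <- function(cate, k = 10) {
  x <- cate$cate_mean
  n <- length(x)
  assert_that(k >= 2, "`k` must be >= 2")
  if (n < k) abort(sprintf("need at least k = %d observations, got %d", k, n))
  if (length(unique(x)) == 1)
    warn("all predicted CATEs are equal; bins follow input order")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * k / n))
}

#' Convert HbA1c between IFCC and NGSP units
#'
#' `NGSP% = 0.09148 * IFCC(mmol/mol) + 2.152`.
#'
#' @param mmol_mol HbA1c in IFCC mmol/mol (non-negative).
#' @param digits Optional rounding of the result.
#' @return HbA1c in NGSP percent.
#' @export
hba1c_units <- function(mmol_mol, digits = NULL) {
  assert_that(all(mmol_mol >= 0), "HbA1c must be non-negative")
  pct <- 0.09148 * mmol_mol + 2.152
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}
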