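# One-hot encoding of predictor frames into the numeric matrices the tree
# samplers consume. Categorical predictors expand to one indicator per level
# (trees can isolate any level); ordinal counts stay numeric.

make_encoder <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("predictors not found in data: ",
                 paste(missing_cols, collapse = ", ")))
  columns <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) {
      lev <- if (is.factor(x)) levels(x) else sort(unique(x))
      columns[[v]] <- list(type = "categorical", levels = lev)
    } else {
      columns[[v]] <- list(type = "numeric")
    }
  }
  structure(list(vars = vars, columns = columns), class = "bcf_encoder")
}

encode_matrix <- function(data, enc) {
  cols <- list()
  src <- character()
  for (v in enc$vars) {
    if (!v %in% names(data))
      abort(paste0("newdata is missing predictor `", v, "`"))
    x <- data[[v]]
    spec <- enc$columns[[v]]
    if (spec$type == "categorical") {
      x <- as.character(x)
      bad <- setdiff(unique(x[!is.na(x)]), spec$levels)
      if (length(bad) > 0)
        abort(paste0("unseen level(s) for `", v, "`: ",
                     paste(bad, collapse = ", ")))
      for (lev in spec$levels) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
        src <- c(src, v)
      }
    } else {
      cols[[v]] <- as.numeric(x)
      src <- c(src, v)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "source_var") <- src
  X
}

# candidate cutpoints per encoded column: observed unique values, thinned to
# at most max_cuts quantiles, excluding the maximum (a split there would
# leave an empty right child)
cutpoint_list <- function(X, max_cuts = 100) {
  lapply(seq_len(ncol(X)), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) > max_cuts + 1)
      u <- sort(unique(quantile(X[, j], probs = seq(0, 1, length.out = max_cuts + 1),
                                type = 1, names = FALSE)))
    if (length(u) > 1) u <- u[-length(u)]
    u
  })
}

#' Candidate predictor sets for the treatment selection model
#'
#' `full_predictor_set()` is the schema of routine clinical features used as
#' candidates for both model surfaces; `mu_predictor_set()` additionally
#' contains the outcome-month covariate, which enters the prognostic surface
#' only (it modifies achieved HbA1c, not the arm contrast) and is fixed at 12
#' months at prediction time.
#'
#' @return Character vector of column names.
#' @export
full_predictor_set <- function() {
  c("age", "dm_duration", "sex", "ethnicity", "imd_quintile", "smoking",
    "ndrugs_ever", "ncurrtx", "hba1c_baseline", "bmi", "egfr", "hdl", "alt",
    "albumin", "bilirubin", "tchol", "map", "heart_failure", "ihd", "pad",
    "neuropathy", "retinopathy")
}

#' @rdname full_predictor_set
#' @export
mu_predictor_set <- function() {
  c(full_predictor_set(), "outcome_month")
}
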