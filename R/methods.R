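#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bayesian causal forest fit
#'
#' Returns one row per candidate variable and forest with its posterior mean
#' splitting probability, the basis of variable selection.
#'
#' @param x A `bcf_fit`.
#' @param ... Unused.
#' @return A tibble with `forest`, `variable`, `split_probability`.
#' @export
tidy.bcf_fit <- function(x, ...) {
  sel <- select_variables(x)
  tibble::as_tibble(sel[, c("forest", "variable", "split_probability")])
}

#' @rdname tidy.bcf_fit
#' @export
glance.bcf_fit <- function(x, ...) {
  cate <- -rowMeans(x$tau)
  tibble::tibble(n = x$n, n_glp1ra = sum(x$z == 1), n_sglt2i = sum(x$z == 0),
                 n_draws = ncol(x$mu), sigma = mean(x$sigma),
                 mean_cate = mean(cate), sd_cate = sd(cate))
}

#' Tidy a propensity fit
#'
#' @param x A `propensity_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-variable posterior mean split proportions;
#'   `glance()`: one row with sample size, draws and discrimination.
#' @export
tidy.propensity_fit <- function(x, ...) {
  cnt <- x$split_counts
  tot <- rowSums(cnt)
  pr <- colMeans(cnt / ifelse(tot == 0, 1, tot))
  agg <- tapply(pr, x$source_var, sum)
  tibble::tibble(variable = names(agg), split_probability = as.numeric(agg))
}

#' @rdname tidy.propensity_fit
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_draws = nrow(x$split_counts), auc = x$auc,
                 pihat_min = min(x$pihat), pihat_max = max(x$pihat))
}
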