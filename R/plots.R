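#' Plot the distribution of predicted CATEs
#'
#' Histogram of posterior-mean predicted HbA1c differences between drug
#' classes; negative values reflect a predicted benefit on SGLT2i, positive
#' on GLP1-RA.
#'
#' @param object A `cate_summary` from [predict_cate()].
#' @param binwidth Histogram bin width in mmol/mol.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cate_summary <- function(object, binwidth = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cate_mean)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Predicted HbA1c difference, SGLT2i − GLP1-RA (mmol/mol)",
      y = "Individuals",
      title = "Predicted conditional average treatment effects",
      subtitle = "negative: SGLT2i benefit; positive: GLP1-RA benefit") +
    ggplot2::theme_minimal()
}

#' Plot subgroup ATE calibration against predicted CATE
#'
#' Subgroup average treatment effects (with 95% credible intervals) against
#' the subgroup mean predicted CATE; the dashed identity line is perfect
#' calibration.
#'
#' @param object A `calibration_summary` from [calibration_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_summary <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$predicted_cate,
                                    y = .data$ate_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ate_lower,
                                        ymax = .data$ate_upper),
                           width = 0.1, colour = "grey35") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Mean predicted CATE (mmol/mol)",
      y = "Adjusted subgroup ATE (mmol/mol)",
      title = "Calibration of predicted CATE",
      subtitle = sprintf("slope %.2f, intercept %.2f; %d/%d intervals cover",
                         object$slope, object$intercept, object$n_covered,
                         object$n_bins)) +
    ggplot2::theme_minimal()
}

#' Plot benefit-subgroup proportions
#'
#' @param subgroups Factor from [assign_benefit_subgroups()].
#' @return A ggplot object.
#' @export
plot_benefit_subgroups <- function(subgroups) {
  tab <- tibble::tibble(subgroup = factor(subgroups,
                                          levels = levels(subgroups)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$subgroup)) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(.data$count) /
                                     sum(ggplot2::after_stat(.data$count)) * 100),
                      fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Individuals (%)",
                  title = "Predicted benefit subgroups") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
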