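#' Plot predicted versus observed survival curves
#'
#' Draws each group's model-predicted survival curve over the observed
#' Kaplan-Meier step curve, one panel per group — the standard visual
#' calibration check for the calculator.
#'
#' @param object A `validation_report` (or a long curve tibble from
#'   [export_curves()]).
#' @param groups Optional subset of groups to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, groups = NULL, ...) {
  plot_survival_curves(object$curves, groups = groups) +
    ggplot2::labs(subtitle = object$label)
}

#' @rdname autoplot.validation_report
#' @param curves Long tibble from [export_curves()].
#' @export
plot_survival_curves <- function(curves, groups = NULL) {
  if (!is.null(groups)) {
    curves <- dplyr::filter(curves, .data$group %in% as_group_factor(groups))
  }
  obs <- dplyr::filter(curves, .data$curve == "observed")
  pred <- dplyr::filter(curves, .data$curve == "predicted")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(data = obs,
                       ggplot2::aes(colour = "observed (KM)")) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(colour = "predicted (Gompertz)")) +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from baseline", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a life-expectancy table
#'
#' Point estimates of median life expectancy per risk group with 95%
#' confidence intervals (error bars) and the 50% prediction interval
#' (whiskers), as produced by [life_expectancy_table()].
#'
#' @param object A tibble from [life_expectancy_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_le_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$t50)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$pi_low,
                                         ymax = .data$pi_high),
                            linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$t50_low,
                                          ymax = .data$t50_high),
                             linewidth = 0.8, fatten = 2) +
    ggplot2::labs(x = "Risk points", y = "Median life expectancy (years)",
                  caption = "bars: 95% CI; grey whiskers: 50% prediction interval") +
    ggplot2::theme_minimal()
}
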