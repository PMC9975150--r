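#' Plot Kaplan-Meier curves
#'
#' Step curves of survival probability per group, with censoring marks.
#'
#' @param object An `irrs_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot irrs_km
#' @export
autoplot.irrs_km <- function(object, ...) {
  start <- object |>
    group_by(.data$group) |>
    summarise(time = 0, estimate = 1, .groups = "drop")
  cens <- filter(object, .data$n_censor > 0)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$estimate, colour = .data$group)) +
    ggplot2::geom_step(data = bind_rows(start, object)) +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.5, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot decision-curve net benefit
#'
#' @param object An `irrs_dca` tibble from [dca_net_benefit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot irrs_dca
#' @export
autoplot.irrs_dca <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$threshold, .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Observed (Kaplan-Meier) event probability against mean predicted risk
#' per bin, with the identity line.
#'
#' @param object An `irrs_calibration` tibble from [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot irrs_calibration
#' @export
autoplot.irrs_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted event probability",
                  y = "Observed event probability (KM)") +
    ggplot2::theme_minimal()
}

#' Plot model pair coefficients
#'
#' Horizontal bar chart of the final cell-pair coefficients: positive
#' bars mark pair configurations that increase hazard, negative bars
#' protective ones.
#'
#' @param object An `irrs_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot irrs_model
#' @export
autoplot.irrs_model <- function(object, ...) {
  d <- mutate(tidy(object),
              pair = stats::reorder(.data$pair, .data$coef))
  ggplot2::ggplot(d, ggplot2::aes(.data$coef, .data$pair,
                                  fill = .data$coef > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Coefficient (log hazard)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
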