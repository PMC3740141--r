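#' Plot a fitted time-signal curve
#'
#' Raw data, the median-filtered series, the fitted PK-PD model curve and
#' the fitted comparison polynomial, with dose times marked.
#'
#' @param object A [fit_pkpd()] result.
#' @param show_raw Draw the unfiltered samples as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pkpd_fit
#' @export
autoplot.pkpd_fit <- function(object, show_raw = TRUE, ...) {
  d <- object$data
  long <- tidyr::pivot_longer(
    d[, c("time_min", "filtered", "fitted_model", "fitted_poly")],
    -"time_min", names_to = "curve", values_to = "value")
  long$curve <- factor(long$curve,
                       levels = c("filtered", "fitted_model", "fitted_poly"),
                       labels = c("filtered data", "PK-PD model",
                                  "comparison polynomial"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                          colour = .data$curve))
  if (show_raw)
    p <- p + ggplot2::geom_point(data = d,
                                 ggplot2::aes(.data$time_min, .data$signal),
                                 inherit.aes = FALSE, alpha = 0.25, size = 0.4)
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = object$schedule$time_min,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time (min)", y = "signal (imaging units)",
                  colour = NULL,
                  subtitle = sprintf("EC50 = %g, F = %.3g, p = %.3g",
                                     object$estimates$ec50_hat,
                                     object$estimates$f_stat,
                                     object$estimates$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an operating-characteristic rate against noise level
#'
#' Works with the per-cell tibbles returned by [model_fit_sensitivity()] and
#' [ec50_sensitivity()]: one curve per true EC50, noise level on a log axis.
#'
#' @param data A metrics tibble with a noise column (`noise_fraction` or
#'   `noise_sd`), an `ec50_true` column, and one rate column.
#' @param rate Name of the rate column; auto-detected by default.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(data, rate = NULL) {
  if (is.null(rate)) {
    rate <- intersect(c("sensitivity", "ec50_sensitivity", "specificity"),
                      names(data))[1]
    if (is.na(rate)) stop_input("no rate column found in `data`")
  }
  xcol <- intersect(c("noise_fraction", "noise_sd"), names(data))[1]
  if (is.na(xcol)) stop_input("no noise column found in `data`")
  ggplot2::ggplot(data, ggplot2::aes(.data[[xcol]], .data[[rate]],
                                     colour = factor(.data$ec50_true),
                                     group = factor(.data$ec50_true))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (xcol == "noise_fraction")
                    "noise SD (fraction of e_max)" else "noise SD (imaging units)",
                  y = rate, colour = "true EC50") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-output-value EC50 positive predictive value or specificity
#'
#' @param data A tibble from [ec50_ppv()] or [ec50_specificity()].
#' @return A ggplot object.
#' @export
plot_ppv <- function(data) {
  ycol <- intersect(c("ppv", "specificity"), names(data))[1]
  if (is.na(ycol)) stop_input("`data` must have a `ppv` or `specificity` column")
  ggplot2::ggplot(data, ggplot2::aes(factor(.data$ec50_value),
                                     .data[[ycol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "output EC50 value", y = ycol) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
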