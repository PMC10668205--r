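## ggplot2 helpers for the standard cost-effectiveness displays.

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_table Tibble from [ceac()] (`wtp`,
#'   `prob_cost_effective`).
#' @param wtp_ref Optional reference thresholds drawn as vertical lines
#'   (e.g. 1x and 3x per-capita GDP).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table, wtp_ref = NULL) {
  p <- ggplot2::ggplot(ceac_table,
                       ggplot2::aes(x = .data$wtp,
                                    y = .data$prob_cost_effective)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = "Probability drug treatment is cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp_ref)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp_ref, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Incremental cost-effectiveness plane from PSA draws
#'
#' Scatter of per-draw incremental QALYs against incremental costs, with
#' the WTP threshold drawn through the origin.
#'
#' @param psa A `psa_result`.
#' @param wtp Threshold slope to draw; defaults to the parameter set's
#'   GDP anchor.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, wtp = NULL) {
  if (is.null(wtp)) wtp <- psa$wtp_per_gdp
  ggplot2::ggplot(psa$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("WTP threshold $%.0f/QALY", wtp)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_psa Cost-effectiveness plane scatter of the draws.
#' @param object A `psa_result`.
#' @param ... Passed to [plot_psa_scatter()].
#' @export
autoplot.psa_result <- function(object, ...) {
  plot_psa_scatter(object, ...)
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars from the low-input to the high-input incremental net
#' monetary benefit, ordered by range width, with the base-case NMB as a
#' reference line.
#'
#' @param tornado A `tornado_result` from [one_way_tornado()].
#' @param top Number of parameters to display (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  df <- utils::head(tornado, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_low,
                                       xend = .data$nmb_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "base_nmb"),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Incremental NMB at $%.0f/QALY",
                              attr(tornado, "wtp")),
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @describeIn one_way_tornado Tornado diagram of the result.
#' @param object A `tornado_result`.
#' @param ... Passed to [plot_tornado()].
#' @export
autoplot.tornado_result <- function(object, ...) {
  plot_tornado(object, ...)
}

#' Cohort state-occupancy trace plot
#'
#' @param result An `arm_result` from [solve_cohort()] with
#'   `keep_trace = TRUE`.
#' @return A ggplot object of occupancy by clinical state over cycles.
#' @export
plot_cohort_trace <- function(result) {
  tr <- cohort_trace(result)
  tr <- dplyr::summarise(dplyr::group_by(tr, .data$cycle, .data$clinical),
                         occupancy = sum(.data$occupancy),
                         .groups = "drop")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                   colour = .data$clinical)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cycle (years)", y = "State occupancy",
                  colour = "State",
                  title = sprintf("Cohort trace, %s arm", result$arm)) +
    ggplot2::theme_minimal()
}
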