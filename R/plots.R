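#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars from the NMB at each parameter's low bound to the NMB
#' at its high bound, widest swing on top, with a dashed line at the
#' base-case NMB.
#'
#' @param object A `tornado` tibble from [one_way()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tornado <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    label = factor(label, levels = rev(label)),
    nmb_min = pmin(nmb_at_low, nmb_at_high),
    nmb_max = pmax(nmb_at_low, nmb_at_high)
  )
  ggplot2::ggplot(df, ggplot2::aes(y = label)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = nmb_min, xend = nmb_max, yend = label),
      linewidth = 6, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = nmb_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit ($)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Acceptability-curve plot
#'
#' @param object A `ceac_curve` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -wtp,
                              names_to = "strategy",
                              names_prefix = "prob_",
                              values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(wtp, probability, colour = strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cohort-trace plot
#'
#' State occupancy over the model horizon for one strategy.
#'
#' @param object A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trace[, c("cycle", "occupancy_pfs", "occupancy_pd")],
    -cycle, names_to = "state", names_prefix = "occupancy_",
    values_to = "occupancy"
  )
  ggplot2::ggplot(long, ggplot2::aes(cycle, occupancy, colour = state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy",
                  title = object$strategy$name) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tornado
#' @param x Object to plot.
#' @export
plot_tornado <- function(x, ...) autoplot.tornado(x, ...)

#' @rdname autoplot.ceac_curve
#' @param x Object to plot.
#' @export
plot_ceac <- function(x, ...) autoplot.ceac_curve(x, ...)

#' @rdname autoplot.cohort_result
#' @param x Object to plot.
#' @export
plot_trace <- function(x, ...) autoplot.cohort_result(x, ...)
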