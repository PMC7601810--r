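#' Plot a high-fidelity trajectory
#'
#' Total and necrotic volume over time, with dose days optionally marked.
#'
#' @param object A `ca_output` tibble from [run_ca()].
#' @param schedule Optional treatment schedule whose dose days are marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_output <- function(object, schedule = NULL, ...) {
  df <- tidyr::pivot_longer(
    object[c("day", "tumor_volume", "necrotic_volume")],
    -"day", names_to = "series", values_to = "volume")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$volume,
                                        color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = expression(volume ~ (mm^3)),
                  color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(schedule) && nrow(schedule))
    p <- p + ggplot2::geom_vline(xintercept = schedule$day,
                                 linetype = "dotted", alpha = 0.3)
  p
}

#' Plot a design history over its high-fidelity data
#'
#' Chosen scans overlaid on the trajectory they were drawn from, colored by
#' metric.
#'
#' @param object A `design_history`.
#' @param ca_data The high-fidelity trajectory the design ran against.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_history <- function(object, ca_data = NULL, ...) {
  st <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(ca_data))
    p <- p + ggplot2::geom_line(
      data = ca_data, ggplot2::aes(.data$day, .data$tumor_volume),
      color = "grey50")
  dat <- attr(object, "data")
  dat$value_plot <- dat$value
  p + ggplot2::geom_point(
        data = dat,
        ggplot2::aes(.data$day, .data$value_plot, shape = .data$metric),
        size = 2) +
    ggplot2::geom_vline(xintercept = st$day, linetype = "dotted",
                        alpha = 0.4) +
    ggplot2::labs(x = "day", y = expression(volume ~ (mm^3))) +
    ggplot2::theme_minimal()
}

#' Plot posterior interquartile shrinkage across design steps
#'
#' The working picture of calibration progress: the posterior median of
#' `beta` with its interquartile ribbon after each added scan.
#'
#' @param history A `design_history`.
#' @return A ggplot object.
#' @export
plot_iqr_trace <- function(history) {
  st <- tidy(history)
  ggplot2::ggplot(st, ggplot2::aes(.data$step, .data$beta_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$beta_q25,
                                      ymax = .data$beta_q75), alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "design step",
                  y = expression(beta ~ (Gy^-2))) +
    ggplot2::theme_minimal()
}

#' Plot a per-step score table
#'
#' Relative mutual information and penalized score across candidate days
#' for one step of a design run.
#'
#' @param history A `design_history`.
#' @param step Which step's table to show (default 1).
#' @return A ggplot object.
#' @export
plot_score_table <- function(history, step = 1) {
  tabs <- attr(history, "meta")$score_tables
  stopifnot(step >= 1, step <= length(tabs))
  tb <- tabs[[step]]
  df <- tidyr::pivot_longer(tb[c("day", "metric", "r_mi", "score")],
                            c("r_mi", "score"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$value,
                                   linetype = .data$quantity,
                                   color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "candidate day", y = NULL) +
    ggplot2::theme_minimal()
}
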