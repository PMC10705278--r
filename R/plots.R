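#' Plot a tuning curve
#'
#' Populated bins as a line + points over angle; unpopulated bins are gaps.
#'
#' @param object A `tuning_curve` from [heading_tuning()] or
#'   [airflow_tuning()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.tuning_curve <- function(object, ...) {
  ggplot2::ggplot(object[object$populated, ],
                  ggplot2::aes(x = .data$bin_center_deg, y = .data$mean)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90),
                                limits = c(-180, 180)) +
    ggplot2::labs(x = "angle (deg)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Plot a conjunctive heading-by-airflow map
#'
#' @param object A [conjunctive_map()].
#' @param ... Unused.
#' @return A ggplot heatmap (heading on x, airflow direction on y).
#' @exportS3Method
autoplot.conjunctive_map <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$heading_deg,
                                   y = .data$airflow_deg,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "relative heading (deg)", y = "airflow direction (deg)",
                  fill = "mean") +
    ggplot2::theme_minimal()
}

#' Plot phase-nulled bridge profiles
#'
#' Left/right mean PFNa profiles over EPG-relative angle; a peak at 0 means
#' the population vector is aligned with the heading signal, a peak at 180
#' means it is inverted.
#'
#' @param profiles A [phase_null()] result.
#' @return A ggplot object.
#' @export
plot_nulled_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$rel_angle_deg,
                                         y = .data$profile,
                                         color = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(left = "#c0392b", right = "#2471a3")) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "angle relative to EPG phase (deg)", y = "mean signal",
                  color = "bridge side") +
    ggplot2::theme_minimal()
}

#' Plot decoded versus true airflow direction
#'
#' @param decode_table A [decode_protocol()] result.
#' @param which `"rel"` (egocentric) or `"allo"` (allocentric).
#' @return A ggplot object with the identity line.
#' @export
plot_decode <- function(decode_table, which = c("rel", "allo")) {
  which <- match.arg(which)
  x <- decode_table$airflow_direction
  y <- if (which == "rel") decode_table$decoded_rel_deg else {
    circ_diff(decode_table$decoded_allo_deg,
              decode_table$true_allo_deg) + decode_table$airflow_direction
  }
  df <- tibble::tibble(true = x, decoded = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$decoded)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(color = "#6c3483", size = 2) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "true airflow direction (deg)",
                  y = "decoded direction (deg)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.quadratic_io_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$vm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$combined), color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#c0392b") +
    ggplot2::labs(x = "Vm above baseline (mV)", y = "combined output") +
    ggplot2::theme_minimal()
}
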