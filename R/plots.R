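#' Plot an acceleration signal
#'
#' Faceted time-series of the three axes, optionally overlaying detected
#' gait events on the vertical axis.
#'
#' @param object an [accel_signal()].
#' @param events optional `gait_events` tibble to overlay.
#' @param window time range (s) to display; default first 10 s.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accel_signal <- function(object, events = NULL, window = c(0, 10),
                                  ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$time >= window[1], .data$time <= window[2]) |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis",
                        values_to = "accel")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$accel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y",
                        labeller = ggplot2::labeller(axis = c(
                          x = "anterior-posterior",
                          y = "mediolateral",
                          z = "vertical"))) +
    ggplot2::labs(x = "time (s)", y = expression(acceleration ~ (m / s^2)))
  if (!is.null(events)) {
    ev <- dplyr::filter(tibble::as_tibble(events),
                        .data$time >= window[1], .data$time <= window[2]) |>
      dplyr::mutate(axis = "z")
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$time, colour = .data$event),
      linetype = "dashed", alpha = 0.7) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Plot wavelet detection signals
#'
#' Shows the smoothed signal `s1` and its derivative `s2`; IC candidates are
#' `s1` minima, FC candidates `s2` maxima.
#'
#' @param object a `wavelet_signals` tibble.
#' @param window time range (s) to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wavelet_signals <- function(object, window = c(0, 10), ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$time >= window[1], .data$time <= window[2]) |>
    tidyr::pivot_longer(c("s1", "s2"), names_to = "signal")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Group distributions of gait features
#'
#' Box plots of each feature by group label, the standard view for judging
#' which temporal/variability features separate disease from control.
#'
#' @param features feature tibble with `label` and feature columns.
#' @param subset subset keyword or names (default all 16).
#' @return a ggplot object.
#' @export
plot_feature_distributions <- function(features, subset = "all") {
  cols <- if (length(subset) == 1 &&
              subset %in% c("all", "logit8", "rf4", "core4")) {
    feature_subset(subset)
  } else {
    subset
  }
  df <- tidyr::pivot_longer(features, dplyr::all_of(cols),
                            names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~factor(feature, levels = cols), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "seconds")
}

#' Plot a Shapley importance ranking
#'
#' @param object a `shapley_result`.
#' @param ... unused.
#' @return a ggplot bar chart of mean absolute Shapley values.
#' @export
autoplot.shapley_result <- function(object, ...) {
  df <- dplyr::mutate(object$ranking,
                      feature = stats::reorder(.data$feature,
                                               .data$mean_abs_shap))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_shap, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL)
}
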