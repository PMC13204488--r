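#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spike raster
#'
#' One point per spike event, channels on the vertical axis, time on the
#' horizontal.
#'
#' @param object A [spike_raster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_raster <- function(object, ...) {
  ev <- which(unclass(object) == 1L, arr.ind = TRUE)
  df <- tibble::tibble(time_s = (ev[, 2] - 1) * attr(object, "dt"),
                       channel = ev[, 1])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$channel)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "channel") +
    ggplot2::theme_minimal()
}

#' Plot a threshold-density sweep
#'
#' Mean graph density against the correlation threshold, with a +/- 1 SD
#' ribbon across subjects and the biological brain-network density band
#' (3.6-39.3%) shaded for reference.
#'
#' @param object A `density_sweep` tibble from [threshold_density_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_th, .data$mean_density)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 0.036, ymax = 0.393, alpha = 0.1, fill = "blue") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_density - .data$sd_density,
      ymax = .data$mean_density + .data$sd_density), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold", y = "network density") +
    ggplot2::theme_minimal()
}

#' Plot readout training convergence
#'
#' Mean own-class van Rossum distance between the actual and desired output
#' trains over training cycles.
#'
#' @param object A `readout_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.readout_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$cycle, .data$mean_vr_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training cycle", y = "mean van Rossum distance") +
    ggplot2::theme_minimal()
}

#' Plot the mean-weight trace of a simulation
#'
#' @param result A `simulation_result` run with `record_weights = TRUE`.
#' @return A ggplot object.
#' @export
plot_weight_trace <- function(result) {
  if (is.null(result$weight_trace)) {
    stop_input("run the simulation with `record_weights = TRUE`")
  }
  ggplot2::ggplot(result$weight_trace,
                  ggplot2::aes(.data$time_ms, .data$mean_g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "mean synaptic weight") +
    ggplot2::theme_minimal()
}
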