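#' Spike raster of a dataset
#'
#' @param data A `spike_tbl`.
#' @param trial_ids Optional subset of trials to draw.
#' @return A ggplot: time on x, channel on y, one facet strip colour per
#'   class.
#' @export
plot_spike_raster <- function(data, trial_ids = NULL) {
  stopifnot(inherits(data, "spike_tbl"))
  ev <- tibble::as_tibble(data)
  if (!is.null(trial_ids)) ev <- ev[ev$trial_id %in% trial_ids, ]
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time, y = .data$channel,
                                   colour = .data$label)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::facet_wrap(~trial_id) +
    ggplot2::labs(x = "time (s)", y = "channel", colour = "class") +
    ggplot2::theme_minimal()
}

#' Membrane-voltage trace of one output neuron
#'
#' @param trial A single trial (one-trial `spike_tbl` or per-channel spike
#'   list).
#' @param weights Per-channel synaptic weights.
#' @param params A [lif_params()].
#' @param grid_dt Plot resolution, seconds.
#' @param duration Trial duration (taken from the `spike_tbl` if available).
#' @return A ggplot of V(t) with the firing threshold marked.
#' @export
plot_voltage_trace <- function(trial, weights, params, grid_dt = 1e-3,
                               duration = NULL) {
  if (inherits(trial, "spike_tbl") && is.null(duration)) {
    duration <- trial_duration(trial)
  }
  tr <- as_one_trial(trial)
  if (is.null(duration)) {
    duration <- max(c(unlist(tr$spikes), 0)) + 10 * params$tau
  }
  grid <- voltage_grid(tr$spikes, duration, grid_dt)
  v <- as.vector(crossprod(psp_matrix(tr$spikes, grid, params),
                           as.double(weights))) + params$v_rest
  df <- tibble::tibble(time = grid, voltage = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$voltage)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$theta, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "membrane voltage") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "mean_accuracy"),
                        linetype = "dashed") +
    ggplot2::labs(x = "test accuracy per repetition", y = "repetitions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  s <- tidy.sweep_result(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$se_accuracy,
      ymax = .data$mean_accuracy + .data$se_accuracy)) +
    ggplot2::labs(x = attr(object, "axis"), y = "mean test accuracy") +
    ggplot2::theme_minimal()
}

#' Per-epoch training accuracy of a fitted network
#'
#' @param object A `tempotron_model`.
#' @param ... Unused.
#' @return A ggplot of training accuracy versus epoch.
#' @export
autoplot.tempotron_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training accuracy") +
    ggplot2::theme_minimal()
}
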