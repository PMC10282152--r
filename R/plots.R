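# ggplot2 views of device traces and simulation results.

#' Plot a pulse-train conductance trace
#' @param trace Tibble from [run_pulse_train()] (or several row-bound
#'   traces distinguished by a `label` column).
#' @return A ggplot object.
#' @export
plot_pulse_train <- function(trace) {
  aes <- if ("label" %in% names(trace)) {
    ggplot2::aes(.data$pulse_index, .data$conductance_S,
                 colour = .data$label)
  } else {
    ggplot2::aes(.data$pulse_index, .data$conductance_S)
  }
  ggplot2::ggplot(trace, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "pulse #", y = "conductance (S)")
}

#' Plot a pinched hysteresis I-V loop
#' @param sweep Tibble from [iv_sweep()].
#' @return A ggplot object.
#' @export
plot_iv <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$voltage_V, .data$current_A,
                                      colour = .data$branch)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "voltage (V)", y = "current (A)")
}

#' Spike raster of a simulation
#'
#' Spikes per neuron over time, with stimulus and cue windows shaded.
#'
#' @param object A `wm_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wm_sim
#' @export
autoplot.wm_sim <- function(object, ...) {
  ev <- object$protocol$events
  gg <- ggplot2::ggplot(object$spikes,
                        ggplot2::aes(.data$t_ms, .data$name,
                                     colour = .data$kind))
  if (nrow(ev)) {
    gg <- gg + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.15
    )
  }
  gg +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = NULL)
}

#' Plot plastic weight trajectories
#' @param result A `wm_sim`.
#' @param kind Synapse kinds to show.
#' @return A ggplot object.
#' @export
plot_weights <- function(result, kind = "feature_to_conj") {
  w <- dplyr::filter(result$weights, .data$kind %in% !!kind)
  ggplot2::ggplot(w, ggplot2::aes(.data$t_ms, .data$weight,
                                  group = .data$syn_id,
                                  colour = factor(.data$post))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (ms)", y = "normalised weight",
                  colour = "post neuron")
}

#' Plot binned conjunctive-neuron firing rates over time
#' @param result A `wm_sim`.
#' @param bin Bin width (ms).
#' @param kind Neuron kind to include.
#' @return A ggplot object.
#' @export
plot_rates <- function(result, bin = 20, kind = "conjunctive") {
  sp <- dplyr::filter(result$spikes, .data$kind == !!kind)
  sp$bin <- floor(sp$t_ms / bin) * bin + bin / 2
  rates <- sp |>
    dplyr::count(.data$name, .data$bin) |>
    dplyr::mutate(rate_hz = .data$n / bin * 1000)
  ggplot2::ggplot(rates, ggplot2::aes(.data$bin, .data$rate_hz,
                                      colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "firing rate (Hz)")
}
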