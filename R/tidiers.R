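#' Tidy an event-triggered average
#'
#' @param x An `eta` object from [event_triggered_average()].
#' @param ... Unused.
#' @return A plain tibble with columns `time`, `mean`, `sem`.
#' @export
tidy.eta <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "mean", "sem")])
}

#' @rdname tidy.eta
#' @export
glance.eta <- function(x, ...) {
  tibble::tibble(n_events = attr(x, "n_events"),
                 recency_weight = attr(x, "recency_weight"),
                 window_pre = -x$time[1],
                 window_post = x$time[nrow(x)] + (x$time[2] - x$time[1]))
}

#' Plot an event-triggered average
#'
#' Mean trace with a standard-error ribbon around the event time.
#'
#' @param object An `eta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eta <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time,
                                             y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "signal",
                  title = sprintf("Event-triggered average (%d events)",
                                  attr(object, "n_events")))
}

#' Tidy a clock mapping
#'
#' @param x A `clock_mapping` from [align_clocks()].
#' @param ... Unused.
#' @return A tibble with one row per fitted term (`offset`, `drift`).
#' @export
tidy.clock_mapping <- function(x, ...) {
  tibble::tibble(term = c("offset", "drift"),
                 estimate = c(x$offset, x$drift))
}

#' @rdname tidy.clock_mapping
#' @export
glance.clock_mapping <- function(x, ...) {
  tibble::tibble(offset = x$offset, drift = x$drift,
                 n_matched = nrow(x$matched), rmse = x$rmse)
}

#' Plot an overlap-noise curve
#'
#' Ratio against window width on a log scale, with the two-channel
#' time-division per-sample window (7.7 ms at 130 Hz) marked for
#' comparison.
#'
#' @param object An `overlap_noise_curve` from [overlap_noise_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_noise_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$width * 1e3,
                                       y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "time_division_window") *
                          1e3, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window width (ms)", y = "normalized overlap noise")
}

#' Summarize an illumination noise comparison
#'
#' @param x An `illumination_noise_comparison` from
#'   [compare_illumination_noise()].
#' @param ... Unused.
#' @return A one-row tibble with the mean CV ratio (the estimated factor
#'   by which time-division could lower its current at matched noise).
#' @export
glance.illumination_noise_comparison <- function(x, ...) {
  tibble::tibble(n_currents = nrow(x),
                 current_ratio = attr(x, "current_ratio"))
}

#' Plot an illumination noise comparison
#'
#' Coefficient of variation against average LED current for the two
#' acquisition schemes.
#'
#' @param object An `illumination_noise_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.illumination_noise_comparison <- function(object, ...) {
  long <- tibble::tibble(
    current = rep(object$current, 2),
    cv = c(object$cv_time_division, object$cv_lockin),
    method = rep(c("time-division", "sinusoidal lock-in"),
                 each = nrow(object))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$current, y = .data$cv,
                                     colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "average LED current (mA)",
                  y = "coefficient of variation")
}

#' Plot a photometry recording
#'
#' Demultiplexed channel voltages against time.
#'
#' @param object A [photometry_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.photometry_recording <- function(object, ...) {
  d <- demultiplex(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$volts)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "baseline-subtracted signal (V)")
}
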