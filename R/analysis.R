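#' Recency-weighted event-triggered average
#'
#' Aligns a signal to repeated event times and averages the per-event
#' traces with an exponential recency weighting: the running mean is
#' updated per event as `mean <- (1 - alpha) * mean + alpha * trace`,
#' oldest to newest, with the first event initializing the mean. Newer
#' events therefore dominate, which is what an online display uses to
#' track a drifting response. `recency_weight = 0` is the documented
#' special case giving the plain unweighted event-triggered average. The
#' dispersion trace is always the unweighted standard error across
#' events.
#'
#' @param data Data frame with a time column and a signal column (e.g.
#'   one channel of [demultiplex()] output).
#' @param events Numeric vector of event times in seconds.
#' @param pre,post Window extent in seconds before and after each event.
#'   Events whose full window falls outside the record are dropped.
#' @param value,time Columns holding the signal and its time stamps
#'   (tidy-eval; defaults `volts` and `time`).
#' @param recency_weight Weight `alpha` in `[0, 1)` given to each new
#'   event (default 0.2).
#' @return A tibble of class `eta` with columns `time` (seconds relative
#'   to the event), `mean` and `sem`, and attributes `n_events` and
#'   `recency_weight`.
#' @export
event_triggered_average <- function(data, events, pre, post,
                                    value = volts, time = time,
                                    recency_weight = 0.2) {
  value <- enquo(value)
  time <- enquo(time)
  x <- eval_tidy(value, data)
  ts <- eval_tidy(time, data)
  if (!is.numeric(x) || !is.numeric(ts) || length(x) != length(ts)) {
    abort("`data` must supply numeric time and signal columns of equal length",
          class = "photomux_config_error")
  }
  if (recency_weight < 0 || recency_weight >= 1) {
    abort("`recency_weight` must lie in [0, 1)",
          class = "photomux_config_error")
  }
  stopifnot_scalar(pre, "pre")
  stopifnot_scalar(post, "post", positive = TRUE)
  rate <- 1 / median(diff(ts))
  n_pre <- round(pre * rate)
  n_post <- round(post * rate)
  rel_idx <- seq(-n_pre, n_post - 1L)
  idx0 <- vapply(events, function(e) which.min(abs(ts - e)), integer(1))
  ok <- idx0 + min(rel_idx) >= 1 & idx0 + max(rel_idx) <= length(x)
  if (!any(ok)) {
    abort("no event has a full window inside the record",
          class = "photomux_empty_result")
  }
  idx0 <- idx0[ok]
  traces <- t(vapply(idx0, function(i) x[i + rel_idx],
                     numeric(length(rel_idx))))
  n_ev <- nrow(traces)
  if (recency_weight == 0) {
    m <- colMeans(traces)
  } else {
    m <- traces[1, ]
    if (n_ev > 1) {
      for (i in 2:n_ev) {
        m <- (1 - recency_weight) * m + recency_weight * traces[i, ]
      }
    }
  }
  sem <- if (n_ev > 1) apply(traces, 2, sd) / sqrt(n_ev) else
    rep(0, ncol(traces))
  out <- tibble::tibble(time = rel_idx / rate, mean = m, sem = sem)
  attr(out, "n_events") <- n_ev
  attr(out, "recency_weight") <- recency_weight
  class(out) <- c("eta", class(out))
  out
}

#' Band-pass filter a photometry signal
#'
#' Zero-phase 4th-order band-pass between `low` and `high` Hz (defaults
#' 0.01 and 20 Hz, the band used for slow fluorescence dynamics),
#' implemented with [zero_phase_filter()]. Removes the DC level and slow
#' drift while preserving signal-band amplitudes and introducing no phase
#' shift.
#'
#' @param x Numeric signal vector.
#' @param low,high Band edges in Hz.
#' @param rate Sampling rate in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_photometry <- function(x, low = 0.01, high = 20, rate) {
  if (low <= 0 || high <= low) {
    abort("need 0 < low < high", class = "photomux_config_error")
  }
  zero_phase_filter(x, c(low, high), "bandpass", rate)
}

#' Align two clocks from shared sync-pulse trains
#'
#' Two systems record the same train of sync pulses (with randomized
#' inter-pulse intervals, so the match is unambiguous) on their own
#' clocks. The pulse trains are matched by sliding the inter-pulse
#' interval sequences over each other and taking the integer lag with
#' the highest normalized cross-correlation (ties broken by smallest
#' residual sum); the matched pulse times are then related by a
#' least-squares affine fit `time_b = offset + drift * time_a`. Unmatched
#' leading/trailing pulses on either train are tolerated.
#'
#' @param pulses_a,pulses_b Pulse times in seconds on clocks A and B
#'   (at least 3 shared pulses).
#' @param tolerance Maximum acceptable absolute residual in seconds for
#'   a matched pulse (default 1 ms).
#' @return A `clock_mapping` object with fields `offset` (s), `drift`
#'   (unitless), `matched` (tibble of paired times and residuals) and
#'   `rmse`. Use [predict()][predict.clock_mapping()] to map times from
#'   clock A to clock B, and [tidy()]/[glance()] for summaries.
#' @examples
#' a <- cumsum(runif(10, 0.5, 1.5))
#' m <- align_clocks(a, 2.5 + a * 1.0001)
#' glance(m)
#' @export
align_clocks <- function(pulses_a, pulses_b, tolerance = 1e-3) {
  a <- sort(as.numeric(pulses_a))
  b <- sort(as.numeric(pulses_b))
  if (length(a) < 3 || length(b) < 3) {
    abort("need at least 3 pulses on each clock",
          class = "photomux_config_error")
  }
  da <- diff(a)
  db <- diff(b)
  # Lag L: a[i] pairs with b[i + L].
  lags <- -(length(a) - 3):(length(b) - 3)
  cand <- lapply(lags, function(L) {
    ia <- max(1, 1 - L):min(length(da), length(db) - L)
    if (length(ia) < 2) return(NULL)
    sa <- da[ia]
    sb <- db[ia + L]
    r <- if (sd(sa) == 0 || sd(sb) == 0) -Inf else stats::cor(sa, sb)
    list(lag = L, r = r, ia = ia)
  })
  cand <- Filter(Negate(is.null), cand)
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "r"),
                     decreasing = TRUE)]
  for (c0 in cand) {
    if (!is.finite(c0$r)) break
    ia <- c(c0$ia, max(c0$ia) + 1L) # interval indices -> pulse indices
    ib <- ia + c0$lag
    fit <- lm(b[ib] ~ a[ia])
    res <- stats::residuals(fit)
    if (max(abs(res)) < tolerance) {
      matched <- tibble::tibble(time_a = a[ia], time_b = b[ib],
                                residual = as.numeric(res))
      return(structure(list(offset = unname(coef(fit)[1]),
                            drift = unname(coef(fit)[2]),
                            matched = matched,
                            rmse = sqrt(mean(res^2)),
                            tolerance = tolerance),
                       class = "clock_mapping"))
    }
  }
  abort(sprintf("no pulse alignment with residuals below %g s", tolerance),
        class = "photomux_alignment_error")
}

#' @export
print.clock_mapping <- function(x, ...) {
  cat(sprintf(
    "<clock_mapping: offset %.6g s, drift %.8g, %d matched pulses, rmse %.3g s>\n",
    x$offset, x$drift, nrow(x$matched), x$rmse))
  invisible(x)
}

#' Map clock-A times onto clock B
#'
#' @param object A `clock_mapping` from [align_clocks()].
#' @param times Times in seconds on clock A.
#' @param ... Unused.
#' @return `offset + drift * times`.
#' @export
predict.clock_mapping <- function(object, times, ...) {
  object$offset + object$drift * times
}

#' Coefficient of variation
#'
#' Standard deviation divided by mean -- the noise metric used to compare
#' acquisition schemes. Scale-invariant: multiplying the signal by a
#' positive constant leaves it unchanged.
#'
#' @param x Numeric vector with non-zero mean.
#' @return `sd(x) / mean(x)`.
#' @export
coefficient_of_variation <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector of length >= 2",
          class = "photomux_config_error")
  }
  m <- mean(x)
  if (m == 0) {
    abort("coefficient of variation is undefined for a zero-mean signal",
          class = "photomux_undefined_metric")
  }
  sd(x) / m
}

#' Rising-edge times of a digital channel
#'
#' Convenience extractor: times (per-channel sample grid) at which a
#' digital input transitions 0 to 1.
#'
#' @param recording A [photometry_recording()].
#' @param channel Digital channel, 1 or 2.
#' @return Numeric vector of edge times in seconds.
#' @export
digital_edges <- function(recording, channel = 1) {
  assert_recording(recording)
  d <- recording[[paste0("digital_", channel)]]
  h <- rec_header(recording)
  idx <- which(diff(c(0L, d)) == 1L)
  (idx - 1) / h$sampling_rate
}
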