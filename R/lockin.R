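#' Zero-phase Butterworth filtering
#'
#' All filtering in the toolkit uses 4th-order zero-phase filters,
#' implemented by running a 2nd-order Butterworth filter in the forward
#' and then the reverse direction. The magnitude response is the squared
#' 2nd-order response (so the gain at a cutoff is 0.5, i.e. -6 dB) and the
#' phase response is identically zero: symmetric features keep their peak
#' sample.
#'
#' @param x Numeric signal vector.
#' @param cutoff Cutoff frequency in Hz (one value for `lowpass` /
#'   `highpass`, a `c(low, high)` pair for `bandpass`).
#' @param kind `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @param rate Sampling rate of `x` in Hz.
#' @return The filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' y <- zero_phase_filter(sin(2 * pi * 20 * t), 20, "lowpass", 1000)
#' max(abs(y[500:1500])) # ~0.5: -6 dB at the cutoff
#' @export
zero_phase_filter <- function(x, cutoff,
                              kind = c("lowpass", "highpass", "bandpass"),
                              rate) {
  kind <- match.arg(kind)
  stopifnot_scalar(rate, "rate", positive = TRUE)
  n_cut <- if (kind == "bandpass") 2L else 1L
  if (length(cutoff) != n_cut || any(cutoff <= 0)) {
    abort(sprintf("`%s` needs %d positive cutoff value(s)", kind, n_cut),
          class = "photomux_config_error")
  }
  if (any(cutoff >= rate / 2)) {
    abort("cutoff frequencies must be below the Nyquist rate",
          class = "photomux_config_error")
  }
  if (kind == "bandpass" && cutoff[1] >= cutoff[2]) {
    abort("bandpass cutoffs must be increasing",
          class = "photomux_config_error")
  }
  type <- switch(kind, lowpass = "low", highpass = "high", bandpass = "pass")
  bf <- signal::butter(2, cutoff / (rate / 2), type = type)
  as.numeric(signal::filtfilt(bf, x))
}

#' Lock-in demodulation configuration
#'
#' @param modulation_frequency Carrier frequency in Hz (e.g. 211 or 531).
#' @param acquisition_rate Sampling rate of the recorded signals in Hz
#'   (default 10 kHz).
#' @param bandpass_halfwidth Half-width in Hz of the bandpass applied
#'   around the carrier in step (1) (default 20 Hz: wide enough for a
#'   20 Hz signal band, narrow enough to separate 211 from 531 Hz).
#' @param lowpass_cutoff Final low-pass cutoff in Hz (default 20).
#' @return A `lockin_config` object.
#' @export
lockin_config <- function(modulation_frequency,
                          acquisition_rate = 1e4,
                          bandpass_halfwidth = 20,
                          lowpass_cutoff = 20) {
  stopifnot_scalar(modulation_frequency, "modulation_frequency",
                   positive = TRUE)
  stopifnot_scalar(acquisition_rate, "acquisition_rate", positive = TRUE)
  stopifnot_scalar(bandpass_halfwidth, "bandpass_halfwidth", positive = TRUE)
  stopifnot_scalar(lowpass_cutoff, "lowpass_cutoff", positive = TRUE)
  if (!(lowpass_cutoff < modulation_frequency &&
        modulation_frequency < acquisition_rate / 2)) {
    abort("need lowpass_cutoff < modulation_frequency < acquisition_rate / 2",
          class = "photomux_config_error")
  }
  if (modulation_frequency - bandpass_halfwidth <= 0) {
    abort("bandpass_halfwidth too wide for the carrier",
          class = "photomux_config_error")
  }
  structure(list(modulation_frequency = modulation_frequency,
                 acquisition_rate = acquisition_rate,
                 bandpass_halfwidth = bandpass_halfwidth,
                 lowpass_cutoff = lowpass_cutoff),
            class = "lockin_config")
}

# Integer-lag cross-correlation alignment: lag (in samples) by which `ref`
# must be delayed to best match `sig`, searched over +/- one carrier period.
best_lag <- function(sig, ref, config) {
  max_lag <- ceiling(config$acquisition_rate / config$modulation_frequency)
  lags <- -max_lag:max_lag
  n <- length(sig)
  score <- vapply(lags, function(k) {
    if (k >= 0) sum(sig[(k + 1):n] * ref[1:(n - k)])
    else sum(sig[1:(n + k)] * ref[(1 - k):n])
  }, numeric(1))
  lags[which.max(score)]
}

shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(rep(x[1], k), x[1:(n - k)])
  else c(x[(1 - k):n], rep(x[n], -k))
}

#' Offline lock-in amplification
#'
#' Recovers the amplitude of a sinusoidally modulated signal in four
#' steps: (1) bandpass filter the recorded modulation reference and the
#' photoreceiver signal around the modulation frequency, (2) apply a time
#' lag to the modulation signal to phase-align it with the photoreceiver
#' signal (integer samples, chosen by cross-correlation), (3) multiply the
#' lagged modulation with the photoreceiver signal, (4) low-pass filter
#' the product at `lowpass_cutoff`. The product is scaled by
#' `2 / reference amplitude` so a unit-amplitude in-phase carrier
#' demodulates to 1.0.
#'
#' The output is insensitive to the reference's initial phase (absorbed by
#' the lag step) and to constant offsets on the photoreceiver signal
#' (rejected by the bandpass).
#'
#' @param photoreceiver Photoreceiver voltage series at the acquisition
#'   rate.
#' @param modulation Recorded modulation reference series, same length.
#' @param config A [lockin_config()].
#' @return A tibble with columns `time` and `amplitude`, with attributes
#'   `lag_samples` and `reference_amplitude`. Edge samples within a few
#'   filter time constants carry filter transients; discard them before
#'   computing statistics (see [lockin_transient()]).
#' @export
lock_in_demodulate <- function(photoreceiver, modulation, config) {
  if (!inherits(config, "lockin_config")) {
    abort("`config` must be a lockin_config", class = "photomux_config_error")
  }
  n <- length(photoreceiver)
  if (length(modulation) != n) {
    abort("signal and modulation series must have equal length",
          class = "photomux_config_error")
  }
  min_len <- 10 * config$acquisition_rate / config$modulation_frequency
  if (n < min_len) {
    abort("record shorter than 10 modulation periods",
          class = "photomux_insufficient_data")
  }
  f <- config$modulation_frequency
  hw <- config$bandpass_halfwidth
  rate <- config$acquisition_rate
  bp_sig <- zero_phase_filter(photoreceiver, c(f - hw, f + hw), "bandpass",
                              rate)
  bp_ref <- zero_phase_filter(modulation, c(f - hw, f + hw), "bandpass",
                              rate)
  lag <- best_lag(bp_sig, bp_ref, config)
  ref_lagged <- shift_series(bp_ref, lag)
  # Reference amplitude from the interior of the bandpassed reference.
  edge <- min(ceiling(lockin_transient(config) * rate), floor(n / 4))
  interior <- (edge + 1):(n - edge)
  a_ref <- sqrt(2) * sd(bp_ref[interior])
  if (!is.finite(a_ref) || a_ref <= 0) {
    abort("modulation reference has no power at the carrier frequency",
          class = "photomux_config_error")
  }
  demod <- zero_phase_filter(bp_sig * ref_lagged, config$lowpass_cutoff,
                             "lowpass", rate) * 2 / a_ref
  out <- tibble::tibble(time = (seq_len(n) - 1) / rate, amplitude = demod)
  attr(out, "lag_samples") <- lag
  attr(out, "reference_amplitude") <- a_ref
  out
}

#' Edge-transient duration of the lock-in filters
#'
#' The demodulation chain cascades three 2nd-order Butterworth stages,
#' each applied forward and reverse; settling to the 0.1% level takes
#' about 15 time constants of the narrowest stage. Samples within this
#' margin of either record edge should be discarded before computing
#' steady-state statistics.
#'
#' @param config A [lockin_config()].
#' @return Duration in seconds.
#' @export
lockin_transient <- function(config) {
  15 / (2 * pi * min(config$lowpass_cutoff, config$bandpass_halfwidth))
}

#' Simulate sinusoidally modulated acquisition
#'
#' Drives each LED with `mean_current * (1 + sin(2 pi f t))` -- 100%
#' modulation depth, modulation amplitude equal to the average value --
#' renders the photoreceiver voltage through the scene and detector
#' model on a fine grid, and samples both the photoreceiver signal and
#' the modulation references at the acquisition rate (default 10 kHz).
#' Scene additive/shot noise is drawn independently per acquired sample.
#'
#' @param scene A [fluorescent_scene()] with one responsivity column per
#'   modulation frequency.
#' @param model A [photoreceiver_model()].
#' @param freqs Modulation frequencies in Hz, one per LED (e.g.
#'   `c(211, 531)`).
#' @param mean_current Average LED current in mA (all LEDs).
#' @param duration Record duration in seconds.
#' @param seed Optional integer seed for the noise draws.
#' @param acquisition_rate Output sampling rate in Hz (default 10 kHz).
#' @param sim_rate Internal simulation rate in Hz (default 100 kHz; must
#'   be a multiple of `acquisition_rate`).
#' @return A tibble with columns `time`, `volts` (detector 1) and one
#'   `ref_<frequency>` column per carrier.
#' @export
simulate_sinusoidal_acquisition <- function(scene, model, freqs,
                                            mean_current, duration,
                                            seed = NULL,
                                            acquisition_rate = 1e4,
                                            sim_rate = 1e5) {
  if (!inherits(scene, "fluorescent_scene")) {
    abort("`scene` must be a fluorescent_scene",
          class = "photomux_config_error")
  }
  if (length(freqs) != ncol(scene$responsivity)) {
    abort("`freqs` must supply one carrier per scene LED",
          class = "photomux_config_error")
  }
  ratio <- sim_rate / acquisition_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`sim_rate` must be an integer multiple of `acquisition_rate`",
          class = "photomux_config_error")
  }
  ratio <- round(ratio)
  t <- seq(0, duration, by = 1 / sim_rate)
  current <- vapply(freqs,
                    function(f) mean_current * (1 + sin(2 * pi * f * t)),
                    numeric(length(t)))
  v <- receiver_voltage_matrix(scene, current, model, t)[, 1]
  keep <- seq(1, length(t), by = ratio)
  t_acq <- t[keep]
  v_acq <- v[keep]
  v_acq <- with_rng_seed(seed, {
    if (scene$shot_noise_coefficient > 0) {
      v_acq <- v_acq + rnorm(length(v_acq),
                             sd = scene$shot_noise_coefficient *
                               sqrt(pmax(v_acq, 0)))
    }
    if (scene$noise_sd_additive > 0) {
      v_acq <- v_acq + rnorm(length(v_acq), sd = scene$noise_sd_additive)
    }
    v_acq
  })
  out <- tibble::tibble(time = t_acq, volts = v_acq)
  for (i in seq_along(freqs)) {
    out[[paste0("ref_", format(freqs[i]))]] <- sin(2 * pi * freqs[i] * t_acq)
  }
  out
}

#' Compare noise of time-division and sinusoidal lock-in acquisition
#'
#' For each average LED current, acquires a steady fluorescent target both
#' ways under matched white additive detector noise and equal average LED
#' current, low-pass filters both outputs at 20 Hz so their bandwidths
#' match, and reports the coefficient of variation of each. Time-division
#' concentrates the same average current into brief pulses (about 10x the
#' instantaneous drive at a 10% duty cycle), so its CV is expected to sit
#' well below the lock-in CV at every current. The `current_ratio`
#' attribute estimates the factor by which the time-division pipeline's
#' current could be reduced at matched noise (CV scales as 1/current).
#'
#' @param scene A [fluorescent_scene()] with `noise_sd_additive > 0`; the
#'   same scene (detector 1, LED 1) is used for both pipelines.
#' @param model A [photoreceiver_model()].
#' @param currents Average LED currents to sweep, in mA. The equivalent
#'   pulse amplitude `current / duty` must stay within 0--100 mA.
#' @param carrier Sinusoidal modulation frequency in Hz (default 211).
#' @param duration_td,duration_lockin Record durations in seconds.
#' @param timings An [acquisition_timings()].
#' @param seed Optional integer seed.
#' @return A tibble of class `illumination_noise_comparison` with columns
#'   `current`, `cv_time_division`, `cv_lockin` and `cv_ratio`, and an
#'   attribute `current_ratio` (mean of `cv_ratio`).
#' @export
compare_illumination_noise <- function(scene,
                                       model = photoreceiver_model(),
                                       currents = 1:5,
                                       carrier = 211,
                                       duration_td = 5,
                                       duration_lockin = 4,
                                       timings = acquisition_timings(),
                                       seed = NULL) {
  if (scene$noise_sd_additive <= 0) {
    abort("`scene` must include additive detector noise",
          class = "photomux_config_error")
  }
  duty <- timings$pulse_width * timings$sampling_rate
  if (any(currents / duty > 100)) {
    abort("a current is too large: pulse amplitude would exceed 100 mA",
          class = "photomux_config_error")
  }
  config <- lockin_config(carrier)
  fs <- timings$sampling_rate
  n_td <- floor(duration_td * fs)
  # Detector-1 views of the scene: LED 1 plus a dark second LED for the
  # two-LED time-division board, LED 1 alone for the sinusoidal pipeline.
  scene_td <- fluorescent_scene(
    responsivity = cbind(scene$responsivity[1, 1], 0),
    activity = c(scene$activity[1], list(1)),
    ambient = scene$ambient[1],
    noise_sd_additive = scene$noise_sd_additive,
    shot_noise_coefficient = scene$shot_noise_coefficient
  )
  scene_1led <- fluorescent_scene(
    responsivity = scene$responsivity[1, 1, drop = FALSE],
    activity = scene$activity[1],
    ambient = scene$ambient[1],
    noise_sd_additive = scene$noise_sd_additive,
    shot_noise_coefficient = scene$shot_noise_coefficient
  )
  rows <- lapply(seq_along(currents), function(i) {
    cur <- currents[i]
    sub_seed <- if (is.null(seed)) NULL else seed + i
    rec <- run_time_division(
      scene_td, model, timings, mode = "1-colour",
      led_amplitudes = c(cur / duty, 0), n_samples = n_td,
      seed = sub_seed
    )
    v_td <- dplyr::filter(demultiplex(rec), .data$channel == 1)$volts
    v_td_f <- zero_phase_filter(v_td, config$lowpass_cutoff, "lowpass", fs)
    edge_td <- ceiling(15 / (2 * pi * config$lowpass_cutoff) * fs)
    cv_td <- coefficient_of_variation(
      v_td_f[(edge_td + 1):(length(v_td_f) - edge_td)])

    acq <- simulate_sinusoidal_acquisition(
      scene_1led, model, freqs = carrier, mean_current = cur,
      duration = duration_lockin,
      seed = if (is.null(sub_seed)) NULL else sub_seed + 1000L
    )
    demod <- lock_in_demodulate(acq$volts, acq[[3]], config)
    edge_li <- ceiling(lockin_transient(config) * config$acquisition_rate)
    amp <- demod$amplitude[(edge_li + 1):(nrow(demod) - edge_li)]
    cv_li <- coefficient_of_variation(amp)
    tibble::tibble(current = cur, cv_time_division = cv_td,
                   cv_lockin = cv_li, cv_ratio = cv_td / cv_li)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "current_ratio") <- mean(out$cv_ratio)
  class(out) <- c("illumination_noise_comparison", class(out))
  out
}
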