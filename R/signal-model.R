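#' LED drive waveform
#'
#' Describes the excitation LED current as a function of time. Pulsed
#' schedules produce rectangular pulses of `pulse_width` seconds once per
#' period; `"anti-phase"` pulses are offset by half a period relative to
#' `"in-phase"` ones (the two LEDs of a time-division sequence).
#' Sinusoidal schedules follow `amplitude * (1 + depth * sin(2 pi f t))`,
#' so at 100% modulation depth the current swings between 0 and twice the
#' mean -- the modulation amplitude equals the average value.
#'
#' @param schedule `"pulsed"`, `"continuous"` or `"sinusoidal"`.
#' @param amplitude Drive current in mA: pulse height for pulsed
#'   schedules, constant level for continuous, mean level for sinusoidal.
#' @param frequency Pulse/modulation frequency in Hz.
#' @param pulse_width Pulse duration in seconds (default 0.75 ms).
#' @param phase `"in-phase"` or `"anti-phase"` (pulsed schedules only).
#' @param modulation_depth Fraction of the mean in `[0, 1]` (sinusoidal
#'   schedules; default 1, i.e. 100%).
#' @return A function of time (seconds) returning current in mA, of class
#'   `led_waveform`, with a `duty_cycle` attribute for pulsed schedules.
#' @examples
#' led <- led_waveform("pulsed", amplitude = 50, frequency = 130)
#' attr(led, "duty_cycle") # 0.0975, i.e. on ~10% of the time
#' @export
led_waveform <- function(schedule = c("pulsed", "continuous", "sinusoidal"),
                         amplitude,
                         frequency = 130,
                         pulse_width = 0.75e-3,
                         phase = c("in-phase", "anti-phase"),
                         modulation_depth = 1) {
  schedule <- match.arg(schedule)
  phase <- match.arg(phase)
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude < 0) {
    abort("`amplitude` must be non-negative", class = "photomux_config_error")
  }
  f <- switch(
    schedule,
    continuous = {
      function(t) rep_len(amplitude, length(t))
    },
    sinusoidal = {
      stopifnot_scalar(frequency, "frequency", positive = TRUE)
      if (modulation_depth < 0 || modulation_depth > 1) {
        abort("`modulation_depth` must lie in [0, 1]",
              class = "photomux_config_error")
      }
      function(t) amplitude * (1 + modulation_depth * sin(2 * pi * frequency * t))
    },
    pulsed = {
      stopifnot_scalar(frequency, "frequency", positive = TRUE)
      stopifnot_scalar(pulse_width, "pulse_width", positive = TRUE)
      duty <- pulse_width * frequency
      if (duty > 0.5) {
        abort(sprintf(
          "duty cycle %.3f exceeds 0.5: anti-phase LEDs cannot share the period",
          duty), class = "photomux_config_error")
      }
      period <- 1 / frequency
      offset <- if (phase == "anti-phase") period / 2 else 0
      function(t) {
        tt <- (t - offset) %% period
        amplitude * as.numeric(tt >= 0 & tt < pulse_width)
      }
    }
  )
  structure(f, class = c("led_waveform", "function"),
            schedule = schedule, amplitude = amplitude,
            frequency = frequency, pulse_width = pulse_width,
            phase = phase, modulation_depth = modulation_depth,
            duty_cycle = if (schedule == "pulsed") pulse_width * frequency
                         else if (schedule == "continuous") 1 else NA_real_)
}

#' Fluorescent scene: the ground-truth light model
#'
#' Describes everything in front of the photoreceiver(s): how strongly each
#' LED's excitation produces voltage-equivalent fluorescence at each
#' detector (`responsivity`, V/mA), slow fluorophore activity traces
#' multiplying each LED's evoked fluorescence, ambient light reaching each
#' detector, and detector noise. The instantaneous light reaching detector
#' d is
#' `ambient_d(t) + sum_l responsivity[d, l] * I_l(t) * activity_l(t)`
#' (volts-equivalent).
#'
#' Additive detector noise is white: it is drawn independently at each
#' sampling instant (each ADC read, or each lock-in acquisition sample)
#' with standard deviation `noise_sd_additive` volts. The optional
#' shot-noise-like term has standard deviation
#' `shot_noise_coefficient * sqrt(signal)`.
#'
#' @param responsivity Numeric matrix, detectors x LEDs, in V/mA. A plain
#'   vector is taken as a single detector row.
#' @param activity List with one entry per LED: a constant, or a function
#'   of time (e.g. from [make_transient_trace()]). Default: constant 1.
#' @param ambient Per-detector ambient light: a numeric vector (volts) or
#'   a list of functions of time. Default 0.
#' @param noise_sd_additive Additive detector noise SD in volts.
#' @param shot_noise_coefficient Volts per sqrt(volt); default 0.
#' @return A `fluorescent_scene` object.
#' @export
fluorescent_scene <- function(responsivity,
                              activity = NULL,
                              ambient = 0,
                              noise_sd_additive = 0,
                              shot_noise_coefficient = 0) {
  if (is.vector(responsivity) && is.numeric(responsivity)) {
    responsivity <- matrix(responsivity, nrow = 1)
  }
  if (!is.matrix(responsivity) || !is.numeric(responsivity) ||
      any(responsivity < 0)) {
    abort("`responsivity` must be a non-negative detectors x LEDs matrix",
          class = "photomux_config_error")
  }
  n_led <- ncol(responsivity)
  n_det <- nrow(responsivity)
  if (is.null(activity)) activity <- rep(list(1), n_led)
  if (!is.list(activity)) activity <- as.list(activity)
  if (length(activity) != n_led) {
    abort("`activity` must have one entry per LED",
          class = "photomux_config_error")
  }
  if (!is.list(ambient)) {
    ambient <- as.list(rep_len(as.numeric(ambient), n_det))
  }
  if (length(ambient) != n_det) {
    abort("`ambient` must have one entry per detector",
          class = "photomux_config_error")
  }
  if (noise_sd_additive < 0 || shot_noise_coefficient < 0) {
    abort("noise parameters must be non-negative",
          class = "photomux_config_error")
  }
  structure(list(responsivity = responsivity,
                 activity = activity,
                 ambient = ambient,
                 noise_sd_additive = noise_sd_additive,
                 shot_noise_coefficient = shot_noise_coefficient),
            class = "fluorescent_scene")
}

# Evaluate a constant-or-function entry on a time grid.
eval_trace <- function(x, t) {
  if (is.function(x)) x(t) else rep_len(as.numeric(x), length(t))
}

#' Photoreceiver transient-response model
#'
#' A linear time-invariant detector with the critically damped
#' second-order low-pass impulse response `h(t) = (t / tau^2) exp(-t / tau)`
#' (unit DC gain times `gain`). `tau` is calibrated so that the response
#' to a long rectangular light pulse first reaches 99% of its plateau
#' `peak_delay` seconds after pulse onset; by symmetry of the critically
#' damped kernel the response also decays below 1% of its plateau
#' `peak_delay` seconds after pulse offset, which must not exceed
#' `settle_time`. The defaults encode a measured photoreceiver that peaked
#' 0.76 ms after light onset and returned to baseline within 2.5 ms of
#' light offset.
#'
#' @param peak_delay Seconds from pulse onset to the response peak
#'   (operationalized as 99% of plateau); default 0.76 ms.
#' @param settle_time Seconds allowed for the response to fall below 1% of
#'   peak after pulse offset; default 2.5 ms.
#' @param gain Unitless DC gain; default 1.
#' @return A `photoreceiver_model` object with fitted time constant `tau`.
#' @export
photoreceiver_model <- function(peak_delay = 0.76e-3,
                                settle_time = 2.5e-3,
                                gain = 1) {
  stopifnot_scalar(peak_delay, "peak_delay", positive = TRUE)
  stopifnot_scalar(settle_time, "settle_time", positive = TRUE)
  stopifnot_scalar(gain, "gain", positive = TRUE)
  # x99 solves (1 + x) exp(-x) = 0.01: the 99% point of the step response.
  x99 <- stats::uniroot(function(x) (1 + x) * exp(-x) - 0.01,
                        c(1, 20), tol = 1e-12)$root
  tau <- peak_delay / x99
  if (tau * x99 > settle_time + 1e-12) {
    abort("settle_time is too short for the requested peak_delay",
          class = "photomux_config_error")
  }
  structure(list(peak_delay = peak_delay, settle_time = settle_time,
                 gain = gain, tau = tau, x99 = x99),
            class = "photoreceiver_model")
}

#' Photoreceiver gain at a frequency
#'
#' Magnitude response of the critically damped detector model,
#' `gain / (1 + (2 pi f tau)^2)`. Sinusoidal carriers are attenuated by
#' this factor (about 2% at 211 Hz, 13% at 531 Hz for the default
#' detector), which matters when predicting demodulated amplitudes.
#'
#' @param model A [photoreceiver_model()].
#' @param frequency Frequency in Hz.
#' @return Magnitude gain (unitless).
#' @export
receiver_gain <- function(model, frequency) {
  model$gain / (1 + (2 * pi * frequency * model$tau)^2)
}

# Discrete impulse-response kernel, normalized so the DC gain is exactly
# `gain` (keeps constant light exactly constant after convolution).
receiver_kernel <- function(model, dt) {
  tk <- seq(0, 14 * model$tau, by = dt)
  k <- (tk / model$tau^2) * exp(-tk / model$tau)
  k * (model$gain / sum(k))
}

# FFT convolution at a 2-3-5-smooth padded length (arbitrary lengths can
# hit large prime factors and degrade R's mixed-radix FFT badly).
fft_convolve_valid <- function(x, k) {
  n <- length(x)
  nk <- length(k)
  nfft <- stats::nextn(n + nk - 1, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nfft - n))) *
                fft(c(k, numeric(nfft - nk))), inverse = TRUE)) / nfft
  y[nk:n]
}

# Convolve each column of `light` (n_t x n_det) with the receiver kernel,
# padding the past with the first value (assumes pre-trial steady state).
receiver_convolve <- function(light, model, dt) {
  k <- receiver_kernel(model, dt)
  nk <- length(k)
  apply(light, 2, function(x) {
    fft_convolve_valid(c(rep(x[1], nk - 1), x), k)
  })
}

# Noiseless detector voltage matrix (n_t x n_det) for LED current matrix
# `current` (n_t x n_led) under `scene` and `model`.
receiver_voltage_matrix <- function(scene, current, model, t) {
  dt <- t[2] - t[1]
  n_det <- nrow(scene$responsivity)
  act <- vapply(seq_along(scene$activity),
                function(l) eval_trace(scene$activity[[l]], t),
                numeric(length(t)))
  evoked <- (current * act) %*% t(scene$responsivity) # n_t x n_det
  amb <- vapply(seq_len(n_det),
                function(d) eval_trace(scene$ambient[[d]], t),
                numeric(length(t)))
  receiver_convolve(evoked + amb, model, dt)
}

#' Simulate the photoreceiver voltage for a scene
#'
#' Renders the instantaneous light reaching each detector (ambient plus
#' responsivity-weighted LED excitation times fluorophore activity),
#' convolves it with the photoreceiver impulse response, and adds noise on
#' the grid. The noiseless output is linear in every LED amplitude.
#'
#' @param scene A [fluorescent_scene()].
#' @param leds List of [led_waveform()] objects, one per scene LED.
#' @param model A [photoreceiver_model()].
#' @param time_grid Strictly increasing time grid in seconds with spacing
#'   at most 0.01 ms (fine enough to resolve the sub-millisecond detector
#'   transient).
#' @param seed Optional integer seed for the noise draws.
#' @return A tibble with columns `time`, `detector`, `volts`.
#' @export
photoreceiver_voltage <- function(scene, leds, model, time_grid,
                                  seed = NULL) {
  if (!inherits(scene, "fluorescent_scene")) {
    abort("`scene` must be a fluorescent_scene",
          class = "photomux_config_error")
  }
  if (inherits(leds, "led_waveform")) leds <- list(leds)
  if (length(leds) != ncol(scene$responsivity)) {
    abort("`leds` must supply one waveform per scene LED",
          class = "photomux_config_error")
  }
  dt <- median(diff(time_grid))
  if (!is.finite(dt) || dt <= 0 || dt > 1e-5 + 1e-12) {
    abort("time grid spacing must be at most 0.01 ms",
          class = "photomux_config_error")
  }
  current <- vapply(leds, function(f) f(time_grid),
                    numeric(length(time_grid)))
  v <- receiver_voltage_matrix(scene, current, model, time_grid)
  v <- with_rng_seed(seed, {
    if (scene$shot_noise_coefficient > 0) {
      v <- v + rnorm(length(v),
                     sd = scene$shot_noise_coefficient * sqrt(pmax(v, 0)))
    }
    if (scene$noise_sd_additive > 0) {
      v <- v + rnorm(length(v), sd = scene$noise_sd_additive)
    }
    v
  })
  tibble::tibble(
    time = rep(time_grid, ncol(v)),
    detector = rep(seq_len(ncol(v)), each = length(time_grid)),
    volts = as.vector(v)
  )
}

#' Generate a calcium-indicator-like activity trace
#'
#' Baseline 1.0 plus double-exponential transients
#' `amplitude * (exp(-t/decay) - exp(-t/rise))` (peak-normalized) at
#' Poisson event times, emulating the slow fluorescence dynamics of a
#' genetically encoded calcium indicator.
#'
#' @param rate Event rate in events/s (0 gives the constant baseline).
#' @param amplitude Peak height of one transient above baseline.
#' @param rise,decay Rise and decay time constants in seconds (defaults
#'   20 ms and 300 ms, GCaMP-like).
#' @param duration Trace duration in seconds (events drawn in `[0, duration]`).
#' @param seed Optional integer seed; the same seed reproduces the trace.
#' @param events Optional explicit event times (overrides the Poisson draw).
#' @return A vectorized function of time of class `activity_trace` with an
#'   `events` attribute.
#' @export
make_transient_trace <- function(rate, amplitude = 1, rise = 0.02,
                                 decay = 0.3, duration = 10, seed = NULL,
                                 events = NULL) {
  if (rate < 0 || amplitude < 0 || rise <= 0 || decay <= 0 || duration <= 0) {
    abort("transient parameters must be positive (rate may be 0)",
          class = "photomux_config_error")
  }
  if (rise >= decay) {
    abort("`rise` must be smaller than `decay`",
          class = "photomux_config_error")
  }
  if (is.null(events)) {
    events <- with_rng_seed(seed, {
      n <- rpois(1, rate * duration)
      sort(runif(n, 0, duration))
    })
  }
  # Peak of exp(-t/decay) - exp(-t/rise) and its value, for normalization.
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  f <- function(t) {
    out <- rep_len(1, length(t))
    for (e in events) {
      dt <- t - e
      on <- dt > 0
      out[on] <- out[on] +
        (amplitude / peak) * (exp(-dt[on] / decay) - exp(-dt[on] / rise))
    }
    out
  }
  structure(f, class = c("activity_trace", "function"),
            events = events, rate = rate, amplitude = amplitude,
            rise = rise, decay = decay)
}
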