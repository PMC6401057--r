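#' ADC specification
#'
#' The acquisition board's ADCs are 12-bit with a 0--3.3 V range;
#' oversampling (64 reads averaged per sample) extends the stored
#' resolution to 15 bits, i.e. `3.3 / 2^15` (about 1.007e-4) volts per
#' division.
#'
#' @param native_bits Native converter resolution (default 12).
#' @param v_max Full-scale voltage (default 3.3).
#' @param output_bits Stored sample resolution (default 15).
#' @return An `adc_spec` object.
#' @export
adc_spec <- function(native_bits = 12, v_max = 3.3, output_bits = 15) {
  stopifnot_scalar(v_max, "v_max", positive = TRUE)
  if (output_bits < native_bits) {
    abort("`output_bits` must be at least `native_bits`",
          class = "photomux_config_error")
  }
  # Full-scale native code maps to the full-scale output count (32767/4095
  # at the defaults, i.e. 8.002: a plain x8 shift could never reach 32767).
  structure(list(native_bits = native_bits, v_max = v_max,
                 output_bits = output_bits,
                 lsb_native = v_max / 2^native_bits,
                 scale = (2^output_bits - 1) / (2^native_bits - 1)),
            class = "adc_spec")
}

#' Volts represented by one output count
#'
#' @param spec An [adc_spec()].
#' @return `v_max / 2^output_bits`, about 1.007e-4 V at the defaults.
#' @export
volts_per_division <- function(spec = adc_spec()) {
  spec$v_max / 2^spec$output_bits
}

#' Quantize voltages with the native converter
#'
#' Floor-to-LSB quantization with clipping at the range edges; the
#' concrete convention used throughout the emulator.
#'
#' @param volts Numeric vector of input voltages.
#' @param spec An [adc_spec()].
#' @return Integer codes in `[0, 2^native_bits - 1]`.
#' @export
quantize_adc <- function(volts, spec = adc_spec()) {
  code <- floor(volts / spec$lsb_native)
  pmin.int(pmax.int(code, 0), 2^spec$native_bits - 1)
}

#' Acquisition timing schedule
#'
#' The pulse/read schedule of the time-division sequence: per channel and
#' per period, a baseline read (both LEDs off) ends exactly at LED onset,
#' the LED stays on for `pulse_width`, and the signal read ends exactly at
#' LED offset. Reading one sample takes
#' `oversample_count / oversample_rate` seconds (0.25 ms at the defaults)
#' and must fit inside the pulse. Channel 2 runs the same schedule offset
#' by half the per-channel period (the two LEDs are in anti-phase).
#'
#' @param sampling_rate Per-channel sampling rate in Hz (default 130, a
#'   7.7 ms period).
#' @param pulse_width LED pulse duration in seconds (default 0.75 ms, a
#'   duty cycle of about 10%).
#' @param oversample_count ADC reads averaged per sample (default 64).
#' @param oversample_rate ADC read rate in Hz (default 256,000).
#' @return An `acquisition_timings` object with derived fields
#'   `read_duration` and `period`.
#' @export
acquisition_timings <- function(sampling_rate = 130,
                                pulse_width = 0.75e-3,
                                oversample_count = 64,
                                oversample_rate = 256e3) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(pulse_width, "pulse_width", positive = TRUE)
  stopifnot_scalar(oversample_rate, "oversample_rate", positive = TRUE)
  read_duration <- oversample_count / oversample_rate
  if (read_duration > pulse_width + 1e-12) {
    abort("sample read duration exceeds the LED pulse width",
          class = "photomux_config_error")
  }
  period <- 1 / sampling_rate
  if (read_duration + pulse_width > period / 2) {
    abort("baseline read plus pulse does not fit in half the period",
          class = "photomux_config_error")
  }
  structure(list(sampling_rate = sampling_rate, pulse_width = pulse_width,
                 oversample_count = oversample_count,
                 oversample_rate = oversample_rate,
                 read_duration = read_duration, period = period),
            class = "acquisition_timings")
}

#' One oversampled ADC sample
#'
#' Reads the input `oversample_count` times at the oversample rate across
#' a window ending `read_duration` after `window_start`, quantizes each
#' read with the native 12-bit converter, averages, and scales to an
#' output count (x8 at the defaults, rounded to nearest). With wideband
#' input noise of at least ~1 native LSB acting as dither, averaging 64
#' reads reduces the read standard deviation 8-fold -- the extra 3 bits of
#' effective resolution.
#'
#' @param voltage A function of time (seconds -> volts), or a data frame
#'   with `time` and `volts` columns (linearly interpolated; reads outside
#'   its range raise a bounds error).
#' @param window_start Read window start time in seconds.
#' @param spec An [adc_spec()].
#' @param timings An [acquisition_timings()].
#' @param dither_sd SD in volts of white noise added independently to each
#'   of the reads (models wideband detector/ADC noise).
#' @param seed Optional seed for the dither draws.
#' @return A single output count in `[0, 2^output_bits - 1]`.
#' @export
adc_oversampled_read <- function(voltage, window_start,
                                 spec = adc_spec(),
                                 timings = acquisition_timings(),
                                 dither_sd = 0, seed = NULL) {
  n <- timings$oversample_count
  t_reads <- window_start + (seq_len(n) - 0.5) / timings$oversample_rate
  if (is.data.frame(voltage)) {
    if (min(t_reads) < min(voltage$time) || max(t_reads) > max(voltage$time)) {
      abort("read window extends beyond the supplied voltage trace",
            class = "photomux_bounds_error")
    }
    v <- approx(voltage$time, voltage$volts, xout = t_reads)$y
  } else if (is.function(voltage)) {
    v <- voltage(t_reads)
  } else {
    v <- rep_len(as.numeric(voltage), n)
  }
  v <- with_rng_seed(seed, {
    if (dither_sd > 0) v + rnorm(n, sd = dither_sd) else v
  })
  codes <- quantize_adc(v, spec)
  count <- round(mean(codes) * spec$scale)
  min(max(count, 0), 2^spec$output_bits - 1)
}

# Quantize a matrix of read voltages (rows = samples, cols = the 64
# oversampled reads) into output counts, vectorized.
oversampled_counts <- function(v_mat, spec) {
  codes <- quantize_adc(v_mat, spec)
  dim(codes) <- dim(v_mat)
  counts <- round(rowMeans(codes) * spec$scale)
  pmin.int(pmax.int(counts, 0), 2^spec$output_bits - 1)
}

#' Run the time-division acquisition sequence
#'
#' Emulates the board's four-step sequence at each per-channel period:
#' read the signal-1 baseline with both LEDs off, turn LED 1 on, read the
#' signal-1 sample ending at LED offset and store sample minus baseline;
#' then the same for signal 2 and LED 2 half a period later. Baseline
#' subtraction makes the stored counts sensitive only to the difference
#' between LED-on and LED-off light, removing ambient light; negative
#' differences clip to 0 (counts are unsigned 15-bit).
#'
#' Scene additive/shot noise is applied independently to every ADC read
#' (white detector noise); with noise disabled the output is exactly
#' linear in LED amplitude for in-phase illumination and exactly zero for
#' anti-phase or continuous illumination.
#'
#' @param scene A [fluorescent_scene()] with (at least) as many detectors
#'   as the mode requires and one responsivity column per LED.
#' @param model A [photoreceiver_model()].
#' @param timings An [acquisition_timings()].
#' @param mode `"2-colour"`: signal 1 from detector 1, signal 2 from
#'   detector 2; `"1-colour"`: both signals from detector 1.
#' @param led_amplitudes Numeric pair, LED 1 and LED 2 pulse amplitude in
#'   mA (0--100).
#' @param n_samples Number of per-channel samples to acquire.
#' @param digital_inputs List of two numeric vectors of rising-edge event
#'   times in seconds; each digital channel is latched high for a period
#'   if an edge fell within it.
#' @param continuous Logical pair: hold the corresponding LED constantly
#'   on at its amplitude instead of pulsing it.
#' @param seed Optional integer seed (identical seeds give identical
#'   recordings).
#' @param sim_rate Internal simulation grid rate in Hz (default 100 kHz).
#' @param subject_id,start_datetime Passed to [recording_header()].
#' @return A [photometry_recording()] of `n_samples` time points.
#' @examples
#' scene <- fluorescent_scene(matrix(c(0.02, 0, 0, 0.02), 2, 2))
#' rec <- run_time_division(scene, n_samples = 5, led_amplitudes = c(50, 50))
#' rec
#' @export
run_time_division <- function(scene,
                              model = photoreceiver_model(),
                              timings = acquisition_timings(),
                              mode = c("2-colour", "1-colour"),
                              led_amplitudes = c(50, 50),
                              n_samples = 130,
                              digital_inputs = list(numeric(0), numeric(0)),
                              continuous = c(FALSE, FALSE),
                              seed = NULL,
                              sim_rate = 1e5,
                              subject_id = "emulator",
                              start_datetime = "1970-01-01T00:00:00") {
  mode <- match.arg(mode)
  if (!inherits(scene, "fluorescent_scene")) {
    abort("`scene` must be a fluorescent_scene",
          class = "photomux_config_error")
  }
  if (length(led_amplitudes) != 2 || any(led_amplitudes < 0) ||
      any(led_amplitudes > 100)) {
    abort("`led_amplitudes` must be two currents in [0, 100] mA",
          class = "photomux_config_error")
  }
  if (n_samples < 1) {
    abort("`n_samples` must be at least 1", class = "photomux_config_error")
  }
  n_det_needed <- if (mode == "2-colour") 2L else 1L
  if (nrow(scene$responsivity) < n_det_needed) {
    abort(sprintf("mode '%s' needs %d detector(s) in the scene",
                  mode, n_det_needed),
          class = "photomux_config_error")
  }
  if (ncol(scene$responsivity) != 2L) {
    abort("the emulator drives 2 LEDs: scene needs 2 responsivity columns",
          class = "photomux_config_error")
  }
  spec <- adc_spec()
  tm <- timings
  # Snap the grid so each per-channel period is an integer number of
  # steps: the pulse/read schedule then has the same grid phase every
  # period, as on the real board where timing is clock-locked. An
  # unsnapped grid lets pulse edges drift across grid phases and injects
  # artificial period-to-period jitter.
  sim_rate <- tm$sampling_rate * max(100, round(sim_rate / tm$sampling_rate))
  dt <- 1 / sim_rate
  n <- as.integer(n_samples)

  # Per-period event times (channel 1); channel 2 is offset by period/2.
  # Baseline read occupies [0, rd) of the period, LED onset at rd,
  # sample read ends at LED offset rd + pw.
  rd <- tm$read_duration
  pw <- tm$pulse_width
  t_end <- n * tm$period
  t <- seq(0, t_end, by = dt)

  onset <- c(rd, rd + tm$period / 2)
  current <- matrix(0, length(t), 2)
  for (l in 1:2) {
    if (isTRUE(continuous[l])) {
      current[, l] <- led_amplitudes[l]
    } else if (led_amplitudes[l] > 0) {
      tt <- (t - onset[l]) %% tm$period
      current[, l] <- led_amplitudes[l] * as.numeric(tt < pw)
    }
  }
  v_det <- receiver_voltage_matrix(scene, current, model, t)

  period_starts <- (seq_len(n) - 1L) * tm$period
  read_offsets <- (seq_len(tm$oversample_count) - 0.5) / tm$oversample_rate

  read_matrix <- function(window_starts, det, noise_draw) {
    times <- outer(window_starts, read_offsets, "+")
    v <- approx(t, v_det[, det], xout = as.vector(times))$y
    dim(v) <- dim(times)
    noise_draw(v)
  }

  rec <- with_rng_seed(seed, {
    noise_draw <- function(v) {
      if (scene$shot_noise_coefficient > 0) {
        v <- v + rnorm(length(v),
                       sd = scene$shot_noise_coefficient * sqrt(pmax(v, 0)))
      }
      if (scene$noise_sd_additive > 0) {
        v <- v + rnorm(length(v), sd = scene$noise_sd_additive)
      }
      v
    }
    analog <- matrix(0L, n, 2)
    for (ch in 1:2) {
      det <- if (mode == "2-colour") ch else 1L
      base_start <- period_starts + onset[ch] - rd
      samp_start <- period_starts + onset[ch] + pw - rd
      base <- oversampled_counts(read_matrix(base_start, det, noise_draw),
                                 spec)
      samp <- oversampled_counts(read_matrix(samp_start, det, noise_draw),
                                 spec)
      analog[, ch] <- as.integer(pmin.int(pmax.int(samp - base, 0),
                                          2^spec$output_bits - 1))
    }
    digital <- vapply(1:2, function(ch) {
      ev <- digital_inputs[[ch]] %||% numeric(0)
      vapply(seq_len(n), function(i) {
        as.integer(any(ev > (i - 1) * tm$period & ev <= i * tm$period))
      }, integer(1))
    }, integer(n))
    if (n == 1L) digital <- matrix(digital, 1L, 2L)
    list(analog = analog, digital = digital)
  })

  header <- recording_header(
    subject_id = subject_id,
    start_datetime = start_datetime,
    acquisition_mode = paste0(substr(mode, 1, 1), "-colour time-division"),
    sampling_rate = tm$sampling_rate,
    led_currents = as.numeric(led_amplitudes),
    volts_per_division = volts_per_division(spec),
    seed = if (is.null(seed)) NA else seed
  )
  photometry_recording(rec$analog[, 1], rec$analog[, 2],
                       rec$digital[, 1], rec$digital[, 2], header)
}

#' Demultiplex a recording into per-channel voltage series
#'
#' Converts stored counts to volts (`count * volts_per_division` from the
#' header) and attaches per-channel time stamps: channel 1 samples at
#' `(i - 1) / sampling_rate`, channel 2 offset by half the per-channel
#' period (the LEDs alternate in anti-phase).
#'
#' @param recording A [photometry_recording()].
#' @return A tibble with columns `time`, `channel` (1 or 2), `volts`,
#'   `counts` and `digital`.
#' @export
demultiplex <- function(recording) {
  assert_recording(recording)
  h <- rec_header(recording)
  n <- nrow(recording)
  period <- 1 / h$sampling_rate
  t1 <- (seq_len(n) - 1) * period
  tibble::tibble(
    time = c(t1, t1 + period / 2),
    channel = rep(1:2, each = n),
    volts = c(recording$analog_1, recording$analog_2) * h$volts_per_division,
    counts = c(recording$analog_1, recording$analog_2),
    digital = c(recording$digital_1, recording$digital_2)
  )
}
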