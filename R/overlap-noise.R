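#' Dolph-Chebyshev window
#'
#' Symmetric equiripple window with all spectral sidelobes at a constant
#' level `attenuation` dB below the mainlobe; normalized to unit peak.
#' Used as the lock-in low-pass impulse response in the overlap-noise
#' analysis because, for a given width, its mainlobe/sidelobe trade-off
#' suppresses an interfering carrier best among common windows.
#'
#' @param length Window length in samples (at least 8).
#' @param attenuation Sidelobe attenuation in dB (default 100).
#' @return Numeric vector of window weights with unit maximum.
#' @export
dolph_chebyshev_window <- function(length, attenuation = 100) {
  if (length < 8) {
    abort("`length` must be at least 8 samples",
          class = "photomux_config_error")
  }
  stopifnot_scalar(attenuation, "attenuation", positive = TRUE)
  w <- signal::chebwin(length, attenuation)
  w / max(w)
}

#' Overlap-noise evaluation specification
#'
#' Defines the numerical experiment quantifying how orthogonal two
#' sinusoidal modulations are over a finite integration window: the
#' target carrier `f_a`, the interfering carrier `f_b` (equal amplitudes),
#' the Dolph-Chebyshev window attenuation, the rate at which the overlap
#' integrals are evaluated, and the number of measurement time points `T`
#' spread uniformly over one beat period of `|f_a - f_b|` (covering all
#' relative phases of the two carriers).
#'
#' @param f_a Target modulation frequency in Hz (default 211).
#' @param f_b Interfering modulation frequency in Hz (default 531).
#' @param attenuation Window sidelobe attenuation in dB (default 100).
#' @param evaluation_rate Sample rate for the discrete integrals in Hz
#'   (default 100 kHz).
#' @param n_placements Number of window placements `T` (default 256).
#' @return An `overlap_noise_spec` object.
#' @export
overlap_noise_spec <- function(f_a = 211, f_b = 531, attenuation = 100,
                               evaluation_rate = 1e5, n_placements = 256) {
  stopifnot_scalar(f_a, "f_a", positive = TRUE)
  stopifnot_scalar(f_b, "f_b", positive = TRUE)
  if (f_a == f_b) {
    abort("`f_a` and `f_b` must differ", class = "photomux_config_error")
  }
  if (evaluation_rate < 10 * max(f_a, f_b)) {
    abort("`evaluation_rate` must be much larger than the carriers",
          class = "photomux_config_error")
  }
  if (n_placements < 2) {
    abort("`n_placements` must be at least 2",
          class = "photomux_config_error")
  }
  structure(list(f_a = f_a, f_b = f_b, attenuation = attenuation,
                 evaluation_rate = evaluation_rate,
                 n_placements = n_placements),
            class = "overlap_noise_spec")
}

#' Normalized overlap noise for one window width
#'
#' Computes the lock-in contamination statistic
#' `sd_T[ integral F(t - T) r(t) b(t) dt ] / mean_T[ integral F(t - T) r(t) a(t) dt ]`
#' where `r` is the unit reference sinusoid phase-locked to the target
#' carrier `a` at `f_a`, `b` is the unit interfering sinusoid at `f_b`,
#' and `F` is a Dolph-Chebyshev window of the given width centred on the
#' measurement time `T`. Integrals are Riemann sums on the evaluation
#' grid; the standard deviation and mean are taken over `n_placements`
#' values of `T` spanning one beat period.
#'
#' @param spec An [overlap_noise_spec()].
#' @param width Window width in seconds (at least 8 samples at the
#'   evaluation rate).
#' @param b_amplitude Amplitude of the interfering sinusoid (default 1;
#'   the statistic is reported for equal unit amplitudes).
#' @param t_origin Absolute time of the first window placement (default
#'   0). Because the placements span a full beat period, the ratio is
#'   invariant to this phase origin.
#' @return The unitless noise-to-signal ratio.
#' @export
normalized_overlap_noise <- function(spec, width, b_amplitude = 1,
                                     t_origin = 0) {
  if (!inherits(spec, "overlap_noise_spec")) {
    abort("`spec` must be an overlap_noise_spec",
          class = "photomux_config_error")
  }
  n <- round(width * spec$evaluation_rate)
  if (n < 8) {
    abort("window width is degenerate at the evaluation rate",
          class = "photomux_config_error")
  }
  w <- dolph_chebyshev_window(n, spec$attenuation)
  beat <- 1 / abs(spec$f_a - spec$f_b)
  placements <- t_origin +
    seq(0, beat, length.out = spec$n_placements + 1)[seq_len(spec$n_placements)]
  k <- (seq_len(n) - (n + 1) / 2) / spec$evaluation_rate
  # Rows: placements T; columns: window samples t = T + k.
  tt <- outer(placements, k, "+")
  r <- sin(2 * pi * spec$f_a * tt)
  wk <- matrix(w, nrow = spec$n_placements, ncol = n, byrow = TRUE)
  num <- rowSums(wk * r * (b_amplitude * sin(2 * pi * spec$f_b * tt))) /
    spec$evaluation_rate
  den <- rowSums(wk * r * sin(2 * pi * spec$f_a * tt)) /
    spec$evaluation_rate
  sd(num) / mean(den)
}

#' Overlap-noise curve over a grid of window widths
#'
#' @param spec An [overlap_noise_spec()].
#' @param widths Window widths in seconds (default a 0.5 ms grid from
#'   0.5 to 50 ms).
#' @return A tibble of class `overlap_noise_curve` with columns `width`
#'   (seconds) and `ratio`. The comparison constant for two-channel
#'   time-division at 130 Hz -- 1/130 s = 7.7 ms per sample -- is attached
#'   as attribute `time_division_window`.
#' @export
overlap_noise_curve <- function(spec = overlap_noise_spec(),
                                widths = seq(0.5e-3, 50e-3, by = 0.5e-3)) {
  widths <- sort(widths)
  ratio <- vapply(widths, function(w) normalized_overlap_noise(spec, w),
                  numeric(1))
  out <- tibble::tibble(width = widths, ratio = ratio)
  attr(out, "spec") <- spec
  attr(out, "time_division_window") <- 1 / 130
  class(out) <- c("overlap_noise_curve", class(out))
  out
}

#' Smallest window width achieving an overlap-noise threshold
#'
#' Scans the width grid in increasing order and returns the first width
#' whose normalized overlap noise falls below `threshold`. For the
#' default 211/531 Hz carriers and a 100 dB window, an overlap-noise SD
#' below 1e-3 of the target signal needs a window of roughly 10 ms.
#'
#' @param spec An [overlap_noise_spec()].
#' @param threshold Ratio threshold in `(0, 1)`.
#' @param widths Candidate widths in seconds (default 0.5--50 ms in
#'   0.5 ms steps).
#' @return The smallest achieving width in seconds.
#' @export
min_window_for_threshold <- function(spec = overlap_noise_spec(),
                                     threshold,
                                     widths = seq(0.5e-3, 50e-3,
                                                  by = 0.5e-3)) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1)", class = "photomux_config_error")
  }
  widths <- sort(widths)
  achieved <- Inf
  for (w in widths) {
    r <- normalized_overlap_noise(spec, w)
    achieved <- min(achieved, r)
    if (r < threshold) return(w)
  }
  abort(sprintf(
    "no width on the grid reaches ratio < %g (minimum achieved: %g)",
    threshold, achieved),
    class = "photomux_not_found_error")
}
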