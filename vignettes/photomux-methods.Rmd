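---
title: "Models and numerical methods behind photomux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind photomux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`photomux` models a time-division multiplexed fiber-photometry
acquisition chain end to end: a ground-truth optical scene, a linear
photoreceiver, an emulated acquisition board with oversampled
baseline-subtracted ADC reads, the competing sinusoidal/lock-in readout,
and the post-acquisition utilities. This vignette explains the models,
the defaults and why they were chosen, the numerical conventions, and
what the package's tests do and do not establish about real hardware.

## The acquisition scheme being modeled

Two excitation LEDs alternate at the per-channel sampling rate
(130 Hz by default, a 7.7 ms period). Per channel and per period the
board:

1. reads a **baseline** with both LEDs off (a 0.25 ms read window ending
   exactly at LED onset),
2. turns the channel's LED on for 0.75 ms,
3. reads the **sample** in a window ending exactly at LED offset, and
4. stores *sample − baseline*.

Each stored value is therefore sensitive only to the light the LED
itself evokes; ambient light and other slow additive terms cancel. Each
read averages 64 conversions of a 12-bit, 0–3.3 V ADC at 256 kHz and
rescales to a 15-bit count, giving 3.3/2^15 ≈ 1.007×10⁻⁴ V per division.

## The fluorescent scene: what the generator emulates

`fluorescent_scene()` is the synthetic world the emulator samples. Light
reaching detector *d* at time *t* is

```
L_d(t) = ambient_d(t) + Σ_l  R[d, l] · I_l(t) · a_l(t)
```

with `R` the detectors × LEDs responsivity matrix (V/mA), `I_l` the LED
current (mA) and `a_l` a unitless fluorophore activity trace.
`make_transient_trace()` builds GCaMP-like activity: baseline 1 plus
peak-normalized double-exponential transients
`amplitude · (e^(−t/decay) − e^(−t/rise))` at Poisson event times.
Defaults — 20 ms rise, 300 ms decay — are typical of the slower
genetically encoded calcium indicators; the transient *rate* and
*amplitude* have no single canonical value and are explicit arguments
everywhere.

Detector noise is **white at the sampling instants**: an independent
Gaussian draw per ADC read (or per 10 kHz lock-in sample) with standard
deviation `noise_sd_additive` volts, plus an optional shot-noise-like
term with SD `shot_noise_coefficient · sqrt(signal)` (off by default,
matching a detector dominated by electronics noise). This wideband-noise
assumption is what makes oversampling pay: with at least ~1 LSB of
dither, averaging 64 reads cuts the read SD by √64 = 8, the "extra
3 bits". It is also what "matched detector noise" means in the
time-division versus lock-in comparison: both pipelines sample the same
white noise process at their own rates.

The generator deliberately does **not** model: photobleaching, motion or
fiber-bending artefacts, LED driver dynamics (current transients are
~1 µs, far below the grid), fluorescence lifetime (~ns, treated as
instantaneous), detector 1/f noise, or firmware timing jitter. Passing
tests therefore demonstrate correctness of the acquisition arithmetic
and signal processing under an idealized linear scene — not robustness
to those artefacts.

## The photoreceiver model

The detector is linear and time-invariant with the critically damped
second-order low-pass impulse response `h(t) = (t/τ²) e^(−t/τ)`. Only
two facts about the real detector's transient are available — its pulse
response peaked 0.76 ms after light onset and returned to baseline
within 2.5 ms of light offset — so the minimal smooth model matching
both was chosen. A critically damped step response is monotone, so
"peaked" is operationalized as *first reaching 99% of the plateau*,
mirroring the <1%-of-peak convention used for "returned to baseline":
τ solves `(1 + x)e^(−x) = 0.01` at `x = peak_delay/τ` (τ ≈ 0.114 ms at
the defaults). By the symmetry of the kernel the response then also
decays below 1% of plateau 0.76 ms after offset, comfortably inside the
2.5 ms constraint, which the constructor verifies. The discrete kernel
is normalized to exactly unit DC gain so constant light stays exactly
constant — this is what makes the continuous-illumination null
measurement exact rather than approximate.

One measurable consequence: sinusoidal carriers are attenuated by
`receiver_gain(model, f) = 1/(1 + (2πfτ)²)` — about 2% at 211 Hz and
13% at 531 Hz — and the lock-in tests account for it.

## Board emulation: numerical conventions

* **Quantization** is floor-to-LSB with clipping at the range edges; the
  64-read mean is scaled by `(2^15 − 1)/(2^12 − 1)` (≈8.002) and rounded
  to nearest, so a full-scale input maps to a full-scale count.
* **Negative baseline-subtracted values clip to 0** (counts are unsigned
  15-bit).
* **Digital inputs** latch high for a period if any rising edge fell
  inside it.
* **Grid phase locking.** The internal simulation grid (nominally
  100 kHz) is snapped so each per-channel period is an integer number of
  grid steps. Without this, LED pulse edges drift across grid phases
  from period to period, injecting an artificial multiplicative jitter
  of order the grid step over the detector time constant; the real
  board's schedule is clock-locked, so snapping is the faithful choice.
  ADC read instants fall between grid points and are linearly
  interpolated — identically in every period.
* **Ambient rejection granularity.** Constant ambient light cancels
  exactly: both reads quantize identically. Ambient that drifts between
  the baseline and sample reads (0.75 ms apart) can flip all 64
  oversampled conversions across one quantizer boundary together, so the
  residual is bounded by one *native* 12-bit code — 8 output counts —
  and is zero in the typical period. The tests assert exactly this.

## Lock-in amplification

`lock_in_demodulate()` implements the four-step offline procedure:
bandpass both the photoreceiver signal and the recorded modulation
reference around the carrier; phase-align the reference by an integer
sample lag chosen by cross-correlation; multiply; low-pass at 20 Hz.
All filtering in the package is zero-phase 4th order: a 2nd-order
Butterworth run forward and reverse (`signal::filtfilt`), so magnitude
is the squared 2nd-order response (gain 0.5 at a cutoff) and phase is
identically zero.

Choices the procedure itself leaves open:

* **Bandpass half-width** (default ±20 Hz): wide enough to pass a 20 Hz
  signal band, narrow enough to separate 211 from 531 Hz.
* **Amplitude convention**: the product is scaled by 2 / (reference
  amplitude), with the reference amplitude estimated as √2 × the SD of
  the band-passed reference interior, so a unit in-phase carrier
  demodulates to 1.0.
* **Lag granularity**: integer samples at the 10 kHz acquisition rate
  (0.1 ms). At 211 Hz this leaves at most ±3.8° of phase error, a ≤0.3%
  amplitude bias — inside the 1% recovery tolerance the tests use.
* **Edge transients**: the cascade of three 2nd-order stages, each
  applied twice, settles to the 0.1% level only after about 15 time
  constants of the narrowest stage (measured on a unit carrier; three
  time constants, a common rule of thumb, still leaves ~12% error).
  `lockin_transient()` returns this margin (≈120 ms at the defaults)
  and all steady-state statistics discard it at both record edges.

`compare_illumination_noise()` runs both pipelines on the same
steady scene at **equal average LED current** — time-division
concentrates that average into 0.75 ms pulses (≈10.3× the instantaneous
drive at 9.75% duty), sinusoidal modulation uses 100% depth so the
modulation amplitude equals the mean — low-passes both outputs at 20 Hz
for equal bandwidth, and reports the coefficient of variation of each.
Only the *ordering* (time-division CV below lock-in CV across the
current sweep) is asserted by the tests; the matched-noise current
ratio is reported but model-dependent, because the real detector's
noise spectrum is not part of the model.

## Overlap noise

The bandwidth of frequency-division multiplexing is set by how long a
lock-in must integrate before two carriers become orthogonal.
`normalized_overlap_noise()` evaluates, for unit-amplitude sinusoids
*a* at `f_a` = 211 Hz (with reference *r* phase-locked to *a*) and *b*
at `f_b` = 531 Hz,

```
sd_T [ ∫ F(t−T) r(t) b(t) dt ]  /  E_T [ ∫ F(t−T) r(t) a(t) dt ]
```

with `F` a Dolph-Chebyshev window (100 dB sidelobe attenuation, unit
peak) of the given width centred on the measurement time `T`.
Numerical choices: integrals are Riemann sums at 100 kHz; `T` takes 256
values spaced uniformly over one beat period `1/|f_a − f_b|` (3.125 ms),
covering every relative phase of the carriers. Neither count is given by
the procedure's definition; doubling either changes the reported ratios
at the sub-percent level, which the phase-origin invariance test bounds.
Two regimes matter for testing: above ~10⁻⁴ the curve decreases
monotonically with width; below that it sits at the window's −100 dB
sidelobe floor and fluctuates, so monotonicity is only asserted above
10× the floor. The package reports alongside the curve the 7.7 ms
(1/130 s) per-sample window of two-channel time-division for comparison.

## Event-triggered averaging

The online display this models favors recent events, so the mean trace
is the exponential recursion `mean ← (1 − α)·mean + α·trace`, applied
oldest-to-newest with the first event initializing the mean (α = 0.2 by
default; the constant used by the original display is not published, so
α is exposed). As α → 0 the recursion freezes at the first event rather
than converging to the unweighted mean, so `recency_weight = 0` is
defined explicitly as the plain event-triggered mean. The dispersion
trace is always the unweighted standard error: weighting expresses
recency preference, not a claim about variance. Events whose window
would leave the record are dropped; if none remain, that is an error
rather than an empty result.

## Clock alignment

Sync pulses with randomized inter-pulse intervals give an unambiguous
match between two systems' clocks. `align_clocks()` slides the two
inter-pulse-interval sequences over each other, ranks integer lags by
normalized cross-correlation (ties and near-ties are resolved by
checking candidates in correlation order and accepting the first whose
fitted residuals beat the tolerance, 1 ms by default), then fits
`time_b = offset + drift · time_a` by least squares on the matched
pulses. For noiseless affine distortions the recovery is exact to
machine precision; unmatched pulses at either train's ends only shorten
the overlap.

## Problem sizes

The test suite and acceptance script run desk-scale problems chosen to
keep the full suite under half a minute while leaving every assertion
well-resolved: emulator sweeps use 4–130 samples per setting, the noise
comparison uses 3–5 s records per current, lock-in checks use 2–4 s at
10 kHz, the oversampling Monte Carlo uses 10⁴ repetitions, and format
checks use recordings up to the full one-hour, 468,000-sample size
(cheap, since they are I/O only).

## Known limitations

* The scene is linear and stationary; no bleaching, motion artefacts or
  detector 1/f noise, so the simulated matched-noise current ratio
  between acquisition schemes should not be read as a hardware
  prediction.
* The photoreceiver model reproduces two printed timing constraints,
  not a measured transfer function; any detector with the same 99%/1%
  times is indistinguishable to it.
* Chunk bit layout, header framing and CSV dialect are explicit
  conventions of this package (documented in `write_ppd()` /
  `write_ppd_csv()`), chosen where the format description is silent;
  files from other producers may differ in exactly those choices.
* The lock-in lag search is integer-sample; sub-sample phase alignment
  would be needed for amplitude accuracy much below 0.3%.
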