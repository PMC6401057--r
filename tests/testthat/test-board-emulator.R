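test_that("oversampled ADC reads hit the range endpoints", {
  full <- adc_oversampled_read(function(t) rep(3.3, length(t)), 0)
  expect_true(full %in% c(32766, 32767)) # allow -1 for rounding convention
  expect_identical(adc_oversampled_read(function(t) rep(0, length(t)), 0), 0)
  expect_equal(volts_per_division(), 3.3 / 2^15)
  expect_equal(volts_per_division(), 1.007e-4, tolerance = 1e-3)

  trace <- tibble::tibble(time = c(0, 1e-4), volts = c(1, 1))
  expect_error(adc_oversampled_read(trace, 1e-4),
               class = "photomux_bounds_error")
})

test_that("averaging 64 dithered reads reduces the read SD about 8-fold", {
  spec <- adc_spec()
  set.seed(101)
  v0 <- 1.65
  reps <- 3000
  single <- quantize_adc(v0 + rnorm(reps, sd = 1.5 * spec$lsb_native), spec)
  avg <- rowMeans(matrix(
    quantize_adc(v0 + rnorm(reps * 64, sd = 1.5 * spec$lsb_native), spec),
    ncol = 64))
  gain_bits <- log2(sd(single) / sd(avg))
  expect_lt(abs(gain_bits - 3), 0.1)
})

test_that("acquisition timing identities hold at the defaults", {
  tm <- acquisition_timings()
  expect_equal(tm$period, 1 / 130)
  expect_equal(tm$period, 7.7e-3, tolerance = 1e-3)
  expect_equal(tm$read_duration, 64 / 256e3)
  expect_equal(tm$read_duration, 0.25e-3)
  expect_equal(tm$pulse_width * tm$sampling_rate, 0.0975)
  expect_error(acquisition_timings(pulse_width = 1e-4),
               class = "photomux_config_error")
  expect_error(acquisition_timings(sampling_rate = 600),
               class = "photomux_config_error")
})

test_that("in-phase illumination is linear in LED current with zero intercept", {
  scene <- two_colour_scene()
  amps <- c(0, 25, 50, 75, 100)
  outs <- vapply(amps, function(a) {
    rec <- run_time_division(scene, led_amplitudes = c(a, 0), n_samples = 4)
    mean(rec$analog_1)
  }, numeric(1))
  fit <- lm(outs ~ amps)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(abs(coef(fit)[1]), 5) # intercept within a few counts of zero
  expect_identical(outs[1], 0)
})

test_that("anti-phase and continuous illumination read exactly zero at every current", {
  # detector 1 responds to both LEDs, so any crosstalk would show up
  scene <- shared_detector_scene()
  for (a in c(0, 25, 50, 75, 100)) {
    anti <- run_time_division(scene, mode = "1-colour",
                              led_amplitudes = c(0, a), n_samples = 4)
    expect_identical(max(abs(anti$analog_1)), 0L)
    cont <- run_time_division(scene, mode = "1-colour",
                              led_amplitudes = c(a, 0),
                              continuous = c(TRUE, FALSE), n_samples = 4)
    expect_identical(max(abs(cont$analog_1)), 0L)
  }
})

test_that("baseline subtraction removes ambient light", {
  # constant ambient: exact zero
  scene <- fluorescent_scene(matrix(c(0.02, 0), 1, 2), ambient = 1.2)
  rec <- run_time_division(scene, mode = "1-colour",
                           led_amplitudes = c(0, 0), n_samples = 10)
  expect_identical(max(abs(rec$analog_1)), 0L)
  # slowly varying ambient (0.1 Hz): residual bounded by one native ADC
  # code (8 output counts), hit only when the drift between the baseline
  # and sample reads crosses a quantizer boundary
  scene2 <- fluorescent_scene(
    matrix(c(0.02, 0), 1, 2),
    ambient = list(function(t) 1 + 0.05 * sin(2 * pi * 0.1 * t))
  )
  rec2 <- run_time_division(scene2, mode = "1-colour",
                            led_amplitudes = c(0, 0), n_samples = 130)
  expect_lte(max(abs(rec2$analog_1)), 8L)
  expect_lte(mean(abs(rec2$analog_1)), 1)
  # ambient offsets the evoked signal by at most one native code
  rec_led <- run_time_division(scene, mode = "1-colour",
                               led_amplitudes = c(50, 0), n_samples = 4)
  scene_dark <- fluorescent_scene(matrix(c(0.02, 0), 1, 2))
  rec_dark <- run_time_division(scene_dark, mode = "1-colour",
                                led_amplitudes = c(50, 0), n_samples = 4)
  expect_lte(max(abs(rec_led$analog_1 - rec_dark$analog_1)), 8L)
})

test_that("channels are independent: each output tracks only its own LED", {
  scene <- two_colour_scene()
  both <- run_time_division(scene, led_amplitudes = c(30, 70), n_samples = 4)
  only1 <- run_time_division(scene, led_amplitudes = c(30, 0), n_samples = 4)
  only2 <- run_time_division(scene, led_amplitudes = c(0, 70), n_samples = 4)
  expect_identical(both$analog_1, only1$analog_1)
  expect_identical(both$analog_2, only2$analog_2)
  expect_identical(only1$analog_2, rep(0L, 4))
  expect_identical(only2$analog_1, rep(0L, 4))
})

test_that("identical seeds give identical recordings; digital inputs latch edges", {
  scene <- two_colour_scene(noise_sd = 2e-3)
  events <- c(0.004, 0.012, 0.0125)
  r1 <- run_time_division(scene, led_amplitudes = c(40, 40), n_samples = 6,
                          digital_inputs = list(events, 0.02), seed = 99)
  r2 <- run_time_division(scene, led_amplitudes = c(40, 40), n_samples = 6,
                          digital_inputs = list(events, 0.02), seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # period i covers ((i-1)/130, i/130]: events in periods 1 and 2 only
  expect_identical(r1$digital_1, c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(r1$digital_2, c(0L, 0L, 1L, 0L, 0L, 0L))
  r3 <- run_time_division(scene, led_amplitudes = c(40, 40), n_samples = 6,
                          digital_inputs = list(events, 0.02), seed = 100)
  expect_false(identical(r1$analog_1, r3$analog_1))
})

test_that("demultiplexing converts counts to volts and staggers channel time stamps", {
  rec <- photometry_recording(c(0L, 1L, 100L), c(5L, 6L, 7L),
                              c(0L, 0L, 1L), c(1L, 0L, 0L))
  d <- demultiplex(rec)
  vpd <- rec_header(rec)$volts_per_division
  ch1 <- d[d$channel == 1, ]
  ch2 <- d[d$channel == 2, ]
  expect_equal(ch1$volts, c(0, 1, 100) * vpd)
  expect_equal(ch1$volts[2], 3.3 / 32768, tolerance = 1e-12)
  expect_equal(ch2$volts, c(5, 6, 7) * vpd)
  expect_equal(ch1$time, (0:2) / 130)
  expect_equal(ch2$time - ch1$time, rep(1 / (2 * 130), 3))
  expect_identical(ch1$digital, c(0L, 0L, 1L))
})

test_that("1-colour mode reads both signals from detector 1", {
  scene <- shared_detector_scene(r1 = 0.02, r2 = 0.01)
  rec <- run_time_division(scene, mode = "1-colour",
                           led_amplitudes = c(40, 40), n_samples = 4)
  expect_gt(mean(rec$analog_1), 0)
  expect_gt(mean(rec$analog_2), 0)
  # signal 2 sees LED 2 through detector 1's (smaller) responsivity
  expect_lt(mean(rec$analog_2), mean(rec$analog_1))
  expect_equal(rec_header(rec)$acquisition_mode, "1-colour time-division")
})
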