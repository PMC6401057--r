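make_signal <- function(duration = 100, rate = 130,
                        f = function(t) rep(0, length(t))) {
  t <- seq(0, duration, by = 1 / rate)
  tibble::tibble(time = t, volts = f(t))
}

test_that("event-triggered averages honor the recency-weighting recursion", {
  rate <- 130
  d <- make_signal(60, rate, function(t) sin(2 * pi * 0.2 * t))
  events <- c(10, 25, 40)

  # constant signal -> flat trace at that constant
  dc <- make_signal(60, rate, function(t) rep(3.3, length(t)))
  e <- event_triggered_average(dc, events, pre = 1, post = 2)
  expect_equal(e$mean, rep(3.3, nrow(e)))
  expect_equal(nrow(e), round(3 * rate))

  # single event: trace equals that event's window exactly
  e1 <- event_triggered_average(d, 25, pre = 1, post = 2)
  i0 <- which.min(abs(d$time - 25))
  expect_equal(e1$mean, d$volts[(i0 - 130):(i0 + 260 - 1)])
  expect_equal(attr(e1, "n_events"), 1L)

  # two events: alpha * newer + (1 - alpha) * older
  alpha <- 0.3
  e2 <- event_triggered_average(d, c(10, 40), pre = 1, post = 2,
                                recency_weight = alpha)
  w10 <- event_triggered_average(d, 10, pre = 1, post = 2)$mean
  w40 <- event_triggered_average(d, 40, pre = 1, post = 2)$mean
  expect_equal(e2$mean, alpha * w40 + (1 - alpha) * w10, tolerance = 1e-12)
  # dispersion is the unweighted standard error
  expect_equal(e2$sem, apply(rbind(w10, w40), 2, sd) / sqrt(2))

  # recency_weight = 0 gives the plain event-triggered mean
  e0 <- event_triggered_average(d, c(10, 40), pre = 1, post = 2,
                                recency_weight = 0)
  expect_equal(e0$mean, (w10 + w40) / 2)

  # small alpha over many statistically identical events approaches it too
  reps <- seq(5, 95, by = 5)
  dp <- make_signal(100, rate, function(t) sin(2 * pi * 1 * t)) # 1 Hz, 5 s spacing -> identical windows
  em <- event_triggered_average(dp, reps, pre = 1, post = 2,
                                recency_weight = 0.01)
  eu <- event_triggered_average(dp, reps, pre = 1, post = 2,
                                recency_weight = 0)
  expect_equal(em$mean, eu$mean, tolerance = 1e-6)

  # events without a full window are dropped; none usable is an error
  expect_error(event_triggered_average(d, 0.1, pre = 1, post = 2),
               class = "photomux_empty_result")
})

test_that("the photometry bandpass removes drift, preserves the signal band and adds no phase shift", {
  rate <- 130
  t <- seq(0, 240, by = 1 / rate)
  mid <- t > 100 & t < 140
  # DC -> ~0 once the edge transients of the 0.01 Hz corner have decayed
  dcout <- bandpass_photometry(rep(1, length(t)), rate = rate)
  expect_lt(max(abs(dcout[mid])), 0.01)
  # mid-band amplitude preserved within 1% (RMS estimate over whole cycles)
  rms_amp <- function(y) sqrt(2 * mean(y[mid]^2))
  y5 <- bandpass_photometry(sin(2 * pi * 5 * t), rate = rate)
  expect_equal(rms_amp(y5), 1, tolerance = 0.01)
  # 20 Hz corner: amplitude ratio 0.5
  y20 <- bandpass_photometry(sin(2 * pi * 20 * t), rate = rate)
  expect_equal(rms_amp(y20), 0.5, tolerance = 0.01)
  # symmetric pulse keeps its peak sample
  g <- exp(-((t - 120)^2) / 2)
  expect_identical(which.max(bandpass_photometry(g, rate = rate)),
                   which.max(g))
  expect_error(bandpass_photometry(g, low = 20, high = 5, rate = rate),
               class = "photomux_config_error")
})

test_that("clock alignment recovers affine distortions exactly", {
  set.seed(21)
  a <- cumsum(runif(25, 0.5, 1.5))
  cases <- list(c(offset = 3.2, drift = 1),
                c(offset = -1.5, drift = 1.0001),
                c(offset = 120, drift = 0.99997))
  for (cs in cases) {
    b <- cs["offset"] + cs["drift"] * a
    m <- align_clocks(a, b)
    expect_equal(m$offset, unname(cs["offset"]), tolerance = 1e-9)
    expect_equal(m$drift, unname(cs["drift"]), tolerance = 1e-9)
    expect_lt(m$rmse, 1e-10)
    expect_equal(predict(m, a), b, tolerance = 1e-9)
  }
})

test_that("clock alignment tolerates unmatched pulses at the train ends", {
  set.seed(22)
  a <- cumsum(runif(30, 0.5, 1.5))
  b_full <- 2.5 + 1.0001 * a
  ref <- align_clocks(a, b_full)
  # 3 extra pulses at the start of one train
  m1 <- align_clocks(a, c(0.05, 0.35, 0.8, b_full))
  expect_equal(m1$offset, ref$offset, tolerance = 1e-9)
  expect_equal(m1$drift, ref$drift, tolerance = 1e-9)
  # ~10% of pulses lost from each train's opposite ends
  m2 <- align_clocks(a[-(1:3)], b_full[1:27])
  expect_equal(m2$drift, ref$drift, tolerance = 1e-9)
  expect_equal(m2$offset, ref$offset, tolerance = 1e-8)
  # unrelated trains fail to align
  set.seed(23)
  expect_error(align_clocks(a, cumsum(runif(30, 0.5, 1.5))),
               class = "photomux_alignment_error")
  expect_error(align_clocks(a[1:2], b_full[1:2]),
               class = "photomux_config_error")
})

test_that("coefficient of variation behaves as SD over mean", {
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  set.seed(31)
  x <- rnorm(20000, mean = 10, sd = 1)
  expect_equal(coefficient_of_variation(x), 0.1, tolerance = 0.02)
  expect_equal(coefficient_of_variation(3 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)),
               class = "photomux_undefined_metric")
})

test_that("digital edge times are extracted on the per-channel clock", {
  rec <- photometry_recording(rep(0L, 6), rep(0L, 6),
                              c(0L, 1L, 1L, 0L, 1L, 0L),
                              c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(digital_edges(rec, 1), c(1, 4) / 130)
  expect_equal(digital_edges(rec, 2), 0)
})
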