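test_that("detrending removes constants and lines, keeps oscillations", {
  t <- seq(0, 59.9, by = 0.1)
  expect_equal(detrend_series(contrast_series(t, rep(0.4, length(t))))$k,
               rep(0, length(t)), tolerance = 1e-12)
  expect_equal(detrend_series(contrast_series(t, 2 * t + 5))$k,
               rep(0, length(t)), tolerance = 1e-9)
  # an oscillation orthogonal to {1, t} on the grid survives intact
  # (oracle: explicit least-squares projection removed beforehand)
  raw <- 0.05 * cos(2 * pi * 1 * t)
  osc <- unname(resid(lm(raw ~ t)))
  out <- detrend_series(contrast_series(t, osc + 0.3 * t + 2))
  expect_lt(sqrt(mean((out$k - osc)^2)), 1e-6)
  expect_lt(abs(mean(out$k)), 1e-10)
  expect_error(detrend_series(contrast_series(c(0, 1, 2), c(1, 2, 3))),
               class = "especkle_too_few_samples")
})

test_that("resampling doubles the grid and passes through the knots", {
  t <- seq(0, 9, by = 1)
  k <- sin(t)
  out <- resample_double(contrast_series(t, k))
  expect_length(out$t, 2 * length(t) - 1)
  expect_equal(out$k[seq(1, 19, by = 2)], k, tolerance = 1e-12)
  expect_true(attr(out, "uniform"))
  # 2N-1 contract at the minimum size
  expect_length(resample_double(contrast_series(0:3, rep(1, 4)))$t, 7)
})

test_that("jittered sinusoid lands on the true frequency bin after resampling", {
  set.seed(8)
  f0 <- 0.5
  t <- seq(0, 60, by = 0.25) + rnorm(241, sd = 0.0125)
  t <- sort(t)
  s <- contrast_series(t, sin(2 * pi * f0 * t))
  sp <- power_spectrum(resample_double(detrend_series(s)))
  pk <- sp$freq[which.max(sp$power[-1]) + 1]
  expect_lt(abs(pk - f0), sp$resolution)
})

test_that("power spectrum locates a pure tone and rejects nonuniform input", {
  t <- seq(0, 60, by = 1 / 21.4)
  s <- contrast_series(t, 0.02 * sin(2 * pi * 3.5 * t) + 0.3)
  sp <- power_spectrum(detrend_series(s))
  pk <- sp$freq[which.max(sp$power[-1]) + 1]
  expect_lt(abs(pk - 3.5), sp$resolution)
  expect_equal(sp$resolution, sp$freq[2] - sp$freq[1])
  # zero series -> all-zero power
  spz <- power_spectrum(contrast_series(t, rep(0, length(t))))
  expect_true(all(spz$power == 0))
  # nonuniform input is refused with instruction to resample
  tn <- c(seq(0, 5, by = 0.5), 5.9, seq(6.5, 10, by = 0.5))
  expect_error(power_spectrum(contrast_series(tn, seq_along(tn))),
               class = "especkle_nonuniform_series")
})

test_that("peak attribution converts Hz to per-minute rates exactly", {
  # uniform 100 s record whose DFT bins land exactly on the tone frequencies
  t <- seq(0, 99.9, by = 0.1)
  k <- sin(2 * pi * 0.13 * t) + 0.6 * sin(2 * pi * 1.15 * t) +
    0.5 * sin(2 * pi * 1.81 * t)
  sp <- power_spectrum(detrend_series(contrast_series(t, k)))
  est <- attribute_peaks(sp, cardiac_band = c(1, 4),
                         respiratory_band = c(0.1, 1))
  expect_identical(est$rate, est$frequency * 60)
  resp <- primary_rate(est, "respiratory")
  expect_equal(resp, 7.8, tolerance = 1e-6)
  card <- sort(est$rate[est$kind == "cardiac"])
  expect_equal(card[1], 69, tolerance = 1e-6)
  expect_equal(card[2], 108.6, tolerance = 1e-6)
  # a 2.5 Hz cardiac peak reads 150 bpm
  k2 <- sin(2 * pi * 2.5 * t)
  sp2 <- power_spectrum(detrend_series(contrast_series(t, k2)))
  expect_equal(primary_rate(attribute_peaks(sp2), "cardiac"), 150,
               tolerance = 1e-6)
})

test_that("bands beyond the native Nyquist are rejected (aliasing guard)", {
  st <- sim_rate_stack(3.5, 5, 40, 1e-2, 110, shape = c(48, 48))
  s <- resample_double(detrend_series(roi_contrast_series(st)))
  sp <- power_spectrum(s)
  expect_equal(sp$nyquist, 2.5)
  expect_error(attribute_peaks(sp, cardiac_band = c(1, 4)),
               class = "especkle_band_beyond_nyquist")
})

test_that("empty bands and overlapping bands are handled", {
  t <- seq(0, 100, by = 0.1)
  sp <- power_spectrum(resample_double(detrend_series(
    contrast_series(t, sin(2 * pi * 2 * t)))))
  est <- attribute_peaks(sp)
  expect_false(any(est$kind == "respiratory"))
  expect_error(attribute_peaks(sp, cardiac_band = c(0.5, 4),
                               respiratory_band = c(0.1, 1)),
               class = "especkle_invalid_band")
})

test_that("null spectra produce no physiological peak calls", {
  # white-noise contrast series: the band maximum stays below an
  # order-statistic bound matched to the bin count, and no peak passes the
  # prominence threshold
  fired <- 0
  for (seed in 1:5) {
    set.seed(seed)
    t <- seq(0, 60, by = 0.1)
    s <- contrast_series(t, rnorm(length(t), 0.3, 0.01))
    sp <- power_spectrum(resample_double(detrend_series(s)))
    band <- sp$freq >= 0.1 & sp$freq <= 4
    expect_lt(max(sp$power[band]) / median(sp$power[band]), 20)
    if (nrow(attribute_peaks(sp)) > 0) fired <- fired + 1
  }
  expect_lte(fired, 1)
})

test_that("cardiac rate is recovered within one spectral bin across seeds", {
  hits <- 0
  for (seed in 1:20) {
    st <- sim_rate_stack(2, 8, 30, 1e-2, 3000 + seed, shape = c(32, 32),
                         cardiac_depth = 0.25)
    est <- rate_chain(st)
    r <- primary_rate(est, "cardiac")
    bin <- 60 / (st$timestamps[n_frames(st)] - st$timestamps[1])
    if (is.finite(r) && abs(r - 120) <= bin) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
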