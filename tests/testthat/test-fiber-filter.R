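# Smooth synthetic background shared across filter tests.
smooth_bg <- function(n = 128, level = 500) {
  matrix(level, n, n) +
    outer(sin(seq(0, 3, length.out = n)), cos(seq(0, 2, length.out = n))) * 50
}

test_that("constant frames pass through unchanged (DC gain 1)", {
  fr <- matrix(937.5, 32, 32)
  out <- remove_fiber_pattern(fr, fiber_filter_spec(0.1, 4))
  expect_equal(out, fr, tolerance = 1e-9)
})

test_that("honeycomb carrier is suppressed >= 20 dB, background < 1 dB", {
  img <- smooth_bg() * fiber_bundle_pattern(c(128, 128), 8, 0.5)
  out <- remove_fiber_pattern(img, fiber_filter_spec(0.06, 4))
  p_in <- Mod(fft(img - mean(img)))^2
  p_out <- Mod(fft(out - mean(out)))^2
  f <- especkle:::radial_freq(128, 128)
  carrier <- abs(f - 0.125) < 0.01
  lowf <- f > 0 & f < 0.02
  expect_lt(10 * log10(sum(p_out[carrier]) / sum(p_in[carrier])), -20)
  expect_gt(10 * log10(sum(p_out[lowf]) / sum(p_in[lowf])), -1)
  expect_equal(mean(out), mean(img), tolerance = 1e-3)
})

test_that("low-pass contract: output power never exceeds input power", {
  set.seed(9)
  fr <- matrix(runif(64 * 64, 0, 4095), 64, 64)
  out <- remove_fiber_pattern(fr, fiber_filter_spec(0.1, 4))
  expect_lte(sum(out^2), sum(fr^2))
})

test_that("filtering is approximately idempotent at the defaults", {
  img <- smooth_bg() * fiber_bundle_pattern(c(128, 128), 8, 0.5)
  spec <- fiber_filter_spec(0.0625, 4)
  once <- remove_fiber_pattern(img, spec)
  twice <- remove_fiber_pattern(once, spec)
  expect_lt(sqrt(mean((twice - once)^2)) / sqrt(mean(once^2)), 0.01)
})

test_that("bundle carrier frequency is recovered from known spacings", {
  f8 <- estimate_core_spacing(smooth_bg() * fiber_bundle_pattern(c(128, 128), 8, 0.5))
  expect_gte(f8, 0.115); expect_lte(f8, 0.135)
  f12 <- estimate_core_spacing(smooth_bg() * fiber_bundle_pattern(c(128, 128), 12, 0.5))
  expect_lt(abs(f12 - 1 / 12) / (1 / 12), 0.10)
})

test_that("pattern-free speckle yields 'no pattern detected'", {
  cfg <- acquisition_config(5e-4, 10, 30, wavelengths = 660,
                            frame_shape = c(64, 64))
  sim <- simulate_stack(cfg, flat_physiology(baseline_correlation_time = 1), 4)
  avg <- apply(sim$stacks[[1]]$frames, c(2, 3), mean)
  expect_true(is.na(estimate_core_spacing(avg)))
  expect_null(auto_filter_spec(sim$stacks[[1]]))
})

test_that("filter spec validation enforces Nyquist and order bounds", {
  expect_error(fiber_filter_spec(0.5, 4), class = "especkle_invalid_filter")
  expect_error(fiber_filter_spec(-0.1, 4), class = "especkle_invalid_filter")
  expect_error(fiber_filter_spec(0.1, 0), class = "especkle_invalid_filter")
  expect_error(remove_fiber_pattern(matrix(1, 8, 8), fiber_filter_spec(0.1, 4)),
               class = "especkle_invalid_frame")
})

test_that("filtering makes the contrast series insensitive to the bundle pattern", {
  cfg <- acquisition_config(5e-4, 10, 100, wavelengths = 660,
                            frame_shape = c(64, 64))
  sim <- simulate_stack(cfg, flat_physiology(baseline_correlation_time = 1), 7)
  clean <- sim$stacks[[1]]
  overlaid <- overlay_fiber_pattern(clean, 8, 0.4)
  spec <- auto_filter_spec(overlaid)
  expect_s3_class(spec, "fiber_filter_spec")
  expect_equal(spec$cutoff, 0.0625, tolerance = 0.15)
  s_clean <- roi_contrast_series(filter_stack(clean, spec))
  s_over <- roi_contrast_series(filter_stack(overlaid, spec))
  rel_rms <- sqrt(mean((s_over$k - s_clean$k)^2)) / sqrt(mean(s_clean$k^2))
  expect_lt(rel_rms, 0.10)
})
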