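test_that("identical seeds reproduce stacks bit-for-bit; seeds matter", {
  cfg <- acquisition_config(1e-3, 10, 6, frame_shape = c(32, 32))
  phy <- physiology_params(heart_rate = 150)
  a <- simulate_stack(cfg, phy, 99)
  b <- simulate_stack(cfg, phy, 99)
  expect_identical(a$stacks[["660"]]$frames, b$stacks[["660"]]$frames)
  expect_identical(a$stacks[["830"]]$frames, b$stacks[["830"]]$frames)
  expect_identical(a$stacks[["660"]]$timestamps, b$stacks[["660"]]$timestamps)
  d <- simulate_stack(cfg, phy, 100)
  expect_false(identical(a$stacks[["660"]]$frames, d$stacks[["660"]]$frames))
})

test_that("ground truth arrays are frame-length and carry the inputs", {
  cfg <- acquisition_config(1e-3, 10, 7, frame_shape = c(32, 32))
  phy <- physiology_params()
  sim <- simulate_stack(cfg, phy, 3)
  gt <- sim$ground_truth
  for (wl in c("660", "830")) {
    expect_length(gt$per_frame_tau_c[[wl]], 7)
    expect_length(gt$timestamps[[wl]], 7)
    expect_equal(nrow(gt$per_frame_chromophores[[wl]]), 7)
  }
  expect_identical(gt$seed, 3)
  expect_s3_class(gt$params, "physiology_params")
})

test_that("expected contrast decreases strictly with exposure at fixed tau_c", {
  # the four intra-operative exposure presets
  presets <- c(5e-4, 1e-3, 1e-2, 2e-2)
  expect_true(all(diff(contrast_model(presets, 2e-3)) < 0))
  measured <- vapply(seq_along(presets), function(i) {
    cfg <- acquisition_config(presets[i], 10, 4, wavelengths = 660)
    sim <- simulate_stack(cfg, flat_physiology(), 2)
    mean(roi_contrast_series(sim$stacks[[1]])$k)
  }, numeric(1))
  expect_true(all(diff(measured) < 0))
})

test_that("halving tau_c (faster flow) lowers contrast", {
  expect_lt(contrast_model(1e-2, 1e-3), contrast_model(1e-2, 2e-3))
  ks <- vapply(c(2e-3, 1e-3), function(tau) {
    cfg <- acquisition_config(1e-2, 10, 4, wavelengths = 660)
    sim <- simulate_stack(cfg, flat_physiology(baseline_correlation_time = tau), 6)
    mean(roi_contrast_series(sim$stacks[[1]])$k)
  }, numeric(1))
  expect_lt(ks[2], ks[1])
})

test_that("short-exposure static speckle intensities are negative-exponential", {
  cfg <- acquisition_config(5e-4, 10, 1, wavelengths = 660,
                            frame_shape = c(512, 512),
                            shot_noise = FALSE, read_noise_sd = 0)
  phy <- flat_physiology(baseline_correlation_time = 1)
  fr <- get_frame(simulate_stack(cfg, phy, 11)$stacks[[1]], 1)
  # stride past the ~2 px speckle grain so samples are decorrelated
  px <- as.numeric(fr[seq(1, 512, by = 5), seq(1, 512, by = 5)])
  expect_gte(length(px), 1e4)
  p <- suppressWarnings(ks.test(px, "pexp", 1 / mean(px))$p.value)
  expect_gt(p, 0.01)
})

test_that("occlusion window raises ROI contrast, release drops it", {
  cfg <- acquisition_config(2e-2, 1.6, 104, wavelengths = 660)
  phy <- flat_physiology(occlusion_window = c(25, 50))
  s <- roi_contrast_series(simulate_stack(cfg, phy, 21)$stacks[[1]])
  base <- mean(s$k[s$t < 23])
  occ <- mean(s$k[s$t > 27 & s$t < 48])
  rel <- mean(s$k[s$t > 52])
  expect_gt(occ, base * 1.2)
  expect_lt(rel, occ * 0.8)
})

test_that("zero modulation leaves the contrast series spectrally flat", {
  st <- sim_rate_stack(0, 10, 30, 1e-2, 109, shape = c(48, 48))
  est <- rate_chain(st)
  expect_equal(nrow(est), 0L)
})

test_that("invalid configurations and physiology are rejected", {
  expect_error(acquisition_config(0.2, 10, 5), class = "especkle_invalid_config")
  expect_error(acquisition_config(1e-3, 10, 5, frame_shape = c(8, 64)),
               class = "especkle_invalid_config")
  expect_error(physiology_params(heart_rate = 20),
               class = "especkle_invalid_physiology")
  expect_error(physiology_params(respiratory_rate = 100),
               class = "especkle_invalid_physiology")
  expect_error(physiology_params(occlusion_window = c(30, 10)),
               class = "especkle_invalid_physiology")
  # occlusion beyond the recording duration
  cfg <- acquisition_config(1e-2, 10, 20, wavelengths = 660)
  expect_error(
    simulate_stack(cfg, physiology_params(occlusion_window = c(1, 100)), 1),
    class = "especkle_invalid_physiology")
})

test_that("interleaved acquisition offsets the 830 nm stream by half a period", {
  cfg <- acquisition_config(1e-2, 10, 8, interleaved = TRUE,
                            timestamp_jitter_sd = 0, frame_shape = c(16, 16))
  sim <- simulate_stack(cfg, physiology_params(), 4)
  dt <- sim$stacks[["830"]]$timestamps - sim$stacks[["660"]]$timestamps
  expect_equal(dt, rep(0.05, 8), tolerance = 1e-9)
})

test_that("fiber pattern overlay is static, hexagonal and depth-limited", {
  pat <- fiber_bundle_pattern(c(128, 128), 8, 0.5)
  expect_true(all(pat >= 0.5 - 1e-12 & pat <= 1 + 1e-12))
  # six-fold symmetric carrier at 1/8 cycles/px: the strongest non-DC
  # spectral pixels all sit on that ring
  p <- Mod(fft(pat - mean(pat)))^2
  f <- especkle:::radial_freq(128, 128)
  top <- order(p, decreasing = TRUE)[1:6]
  expect_true(all(abs(f[top] - 0.125) < 0.01))

  # frame-invariance: overlay on a constant stack leaves no temporal variance
  frames <- array(1000L, dim = c(3, 32, 32))
  st <- speckle_stack(frames, 0:2, 660, 1e-3)
  ov <- overlay_fiber_pattern(st, 8, 0.5)
  expect_identical(ov$frames[1, , ], ov$frames[2, , ])
  expect_identical(ov$frames[1, , ], ov$frames[3, , ])

  # vanishing depth: identity within integer rounding
  ov0 <- overlay_fiber_pattern(st, 8, 1e-9)
  expect_identical(ov0$frames, st$frames)
  expect_error(overlay_fiber_pattern(st, 8, 0), class = "especkle_invalid_pattern")
  expect_error(overlay_fiber_pattern(st, 2, 0.5), class = "especkle_invalid_pattern")
})
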