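test_that("extinction table enforces the isosbestic-straddling sign structure", {
  tab <- extinction_table()
  expect_gt(tab$eps_hb[1], tab$eps_hbo2[1])    # 660 nm: deoxy dominates
  expect_gt(tab$eps_hbo2[2], tab$eps_hb[2])    # 830 nm: oxy dominates
  expect_error(extinction_table(eps_hbo2 = c(0.4, 0.0974)),
               class = "especkle_invalid_extinction")
  expect_error(extinction_table(eps_hb = c(0.3227, 0.2)),
               class = "especkle_invalid_extinction")
  expect_error(extinction_table(eps_hbo2 = c(-1, 1)),
               class = "especkle_invalid_extinction")
})

test_that("frame pairing matches nearest timestamps, each frame used once", {
  mk <- function(t) speckle_stack(array(500L, dim = c(length(t), 16, 16)),
                                  t, 660, 1e-3)
  # interleaved streams at 1.6 fps: constant half-period lag
  t660 <- (0:19) / 1.6
  t830 <- t660 + 1 / 3.2
  pr <- pair_frames(mk(t660), mk(t830), max_lag = 1 / 1.6)
  expect_equal(nrow(pr), 20)
  expect_equal(pr$lag, rep(1 / 3.2, 20), tolerance = 1e-12)
  expect_equal(pr$index660, pr$index830)
  # identical timestamps: zero-lag pairs
  pr0 <- pair_frames(mk(t660), mk(t660), max_lag = 0.1)
  expect_true(all(pr0$lag == 0))
  # disjoint ranges: unalignable
  expect_error(pair_frames(mk(0:9), mk(100:109), max_lag = 1),
               class = "especkle_unalignable")
})

test_that("oxygenation map is a smoothed ratio with exact linearity", {
  set.seed(4)
  a <- matrix(runif(32 * 32, 100, 2000), 32, 32)
  r1 <- oxygenation_map(a, a)
  expect_equal(r1, matrix(1, 32, 32), tolerance = 1e-12)
  expect_equal(oxygenation_map(2 * a, a), 2 * r1, tolerance = 1e-12)
  expect_error(oxygenation_map(a, a[, 1:16]), class = "especkle_shape_mismatch")
  # zero denominator flags NaN
  b <- a; b[1:16, 1:16] <- 0
  expect_true(any(is.nan(oxygenation_map(a, b, 3))))
})

test_that("a high-HbO2 region shifts the ratio as the forward model predicts", {
  tab <- extinction_table()
  d_hbo2 <- 0.5
  i660 <- matrix(1000, 48, 48); i830 <- matrix(800, 48, 48)
  reg <- 17:32
  i660[reg, reg] <- 1000 * exp(-tab$eps_hbo2[1] * d_hbo2)
  i830[reg, reg] <- 800 * exp(-tab$eps_hbo2[2] * d_hbo2)
  m <- oxygenation_map(i660, i830, 3)
  predicted <- exp(-(tab$eps_hbo2[1] - tab$eps_hbo2[2]) * d_hbo2)  # > 1
  expect_gt(predicted, 1)
  ratio_rel <- mean(m[20:29, 20:29]) / mean(m[2:10, 2:10])
  expect_equal(ratio_rel, predicted, tolerance = 1e-6)
})

test_that("Beer-Lambert inversion round-trips forward-generated deltas", {
  tab <- extinction_table()
  E <- rbind(c(tab$eps_hbo2[1], tab$eps_hb[1]),
             c(tab$eps_hbo2[2], tab$eps_hb[2]))
  for (dc in list(c(0.3, -0.1), c(-0.25, 0.4), c(0.01, 0.02))) {
    I0 <- c(1200, 900)
    I1 <- I0 * exp(-as.numeric(E %*% dc))
    out <- chromophore_deltas(c(I0[1], I1[1]), c(I0[2], I1[2]))
    expect_equal(out$d_hbo2[2], dc[1], tolerance = 1e-9)
    expect_equal(out$d_hb[2], dc[2], tolerance = 1e-9)
    expect_equal(out$d_total, out$d_hbo2 + out$d_hb)
    expect_equal(unlist(out[1, c("d_hbo2", "d_hb", "d_total")]),
                 c(d_hbo2 = 0, d_hb = 0, d_total = 0))
  }
})

test_that("gain changes on either detector cancel out of the deltas", {
  set.seed(6)
  i660 <- runif(20, 800, 1200)
  i830 <- runif(20, 600, 1000)
  base <- chromophore_deltas(i660, i830)
  scaled <- chromophore_deltas(i660 * 3.7, i830 * 0.19)
  expect_equal(scaled$d_hbo2, base$d_hbo2, tolerance = 1e-12)
  expect_equal(scaled$d_hb, base$d_hb, tolerance = 1e-12)
})

test_that("nonpositive samples become NaN; degenerate tables are refused", {
  expect_warning(out <- chromophore_deltas(c(100, 0, 100), c(90, 80, 70)),
                 "nonpositive")
  expect_true(is.nan(out$d_hbo2[2]) && !is.nan(out$d_hbo2[3]))
  tab2 <- extinction_table()
  tab2$eps_hbo2 <- tab2$eps_hb   # singular by construction
  expect_error(chromophore_deltas(c(1, 2), c(1, 2), table = tab2),
               class = "especkle_invalid_extinction")
})

test_that("occlusion modes drive chromophores in opposite directions", {
  run <- function(mode) {
    cfg <- acquisition_config(2e-2, 1.6, 104)
    phy <- physiology_params(cardiac_modulation_depth = 0,
                             respiratory_rate = 30,
                             respiratory_modulation_depth = 0.3,
                             occlusion_window = c(25, 50),
                             occlusion_mode = mode)
    sim <- simulate_stack(cfg, phy, 42)
    i660 <- roi_intensity_series(sim$stacks[["660"]])
    i830 <- roi_intensity_series(sim$stacks[["830"]])
    pr <- pair_frames(sim$stacks[["660"]], sim$stacks[["830"]])
    chromophore_deltas(i660$intensity[pr$index660],
                       i830$intensity[pr$index830],
                       t = i660$t[pr$index660])
  }
  av <- run("arteriovenous")
  occ <- av$t > 27 & av$t < 48; base <- av$t < 23
  expect_gt(mean(av$d_hbo2[occ]), mean(av$d_hbo2[base]) + 0.1)
  expect_gt(mean(av$d_total[occ]), mean(av$d_total[base]) + 0.1)
  art <- run("arterial")
  expect_lt(mean(art$d_hbo2[occ]), mean(art$d_hbo2[base]) - 0.1)
})
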