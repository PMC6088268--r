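# Shared builders for simulated fixtures (all generated in code, seeded).

flat_physiology <- function(...) {
  physiology_params(cardiac_modulation_depth = 0,
                    respiratory_modulation_depth = 0, ...)
}

# Single-wavelength stack with the given cardiac/respiratory modulation
# frequencies (Hz; 0 disables that component).
sim_rate_stack <- function(cardiac_hz, fps, duration, exposure, seed,
                           resp_hz = 0, shape = c(64, 64),
                           cardiac_depth = 0.4, resp_depth = 0.3) {
  cfg <- acquisition_config(exposure, fps, round(fps * duration),
                            wavelengths = 660, frame_shape = shape)
  phy <- physiology_params(
    heart_rate = if (cardiac_hz > 0) cardiac_hz * 60 else 180,
    cardiac_modulation_depth = if (cardiac_hz > 0) cardiac_depth else 0,
    respiratory_rate = if (resp_hz > 0) resp_hz * 60 else 36,
    respiratory_modulation_depth = if (resp_hz > 0) resp_depth else 0)
  simulate_stack(cfg, phy, seed)$stacks[[1]]
}

# Detrend -> uniform resample -> FFT -> peak attribution.
rate_chain <- function(stack, cardiac_band = c(1, 4),
                       respiratory_band = c(0.1, 1)) {
  s <- roi_contrast_series(stack)
  attribute_peaks(power_spectrum(resample_double(detrend_series(s))),
                  cardiac_band, respiratory_band)
}

# Brute-force windowed contrast oracle: explicit per-pixel double loop with
# edge-inclusive reflective padding, sd()/mean() per window.
contrast_oracle <- function(frame, w) {
  r <- (w - 1) %/% 2
  nr <- nrow(frame); nc <- ncol(frame)
  ridx <- c(r:1, 1:nr, nr:(nr - r + 1))
  cidx <- c(r:1, 1:nc, nc:(nc - r + 1))
  fp <- frame[ridx, cidx]
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    win <- fp[i:(i + 2 * r), j:(j + 2 * r)]
    m <- mean(win)
    out[i, j] <- if (m == 0) NaN else sd(win) / m
  }
  out
}

# The 25 s flow / 25 s clamp / 15 s release protocol as an idealized step
# series at 1.6 fps.
step_series <- function(noise_sd = 0.01, seed = 5, dt = 0.625,
                        levels = c(0.30, 0.45, 0.30),
                        breaks = c(25, 50), duration = 65) {
  set.seed(seed)
  t <- seq(0, duration - dt, by = dt)
  k <- ifelse(t < breaks[1], levels[1],
              ifelse(t < breaks[2], levels[2], levels[3])) +
    rnorm(length(t), sd = noise_sd)
  contrast_series(t, k)
}
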