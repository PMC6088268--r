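#' Speckle contrast as a function of exposure and correlation time
#'
#' The Lorentzian-velocity (negative-exponential field correlation) model
#' relating spatial speckle contrast K to camera exposure T and speckle
#' correlation time `tau_c`:
#' \deqn{K^2(T, \tau_c) = \frac{\tau_c}{2T}\left(1 - e^{-2T/\tau_c}\right)}
#' K decreases monotonically with T at fixed `tau_c`, and with decreasing
#' `tau_c` (faster flow) at fixed T: low contrast marks fast blood flow.
#'
#' @param exposure_time Exposure T in seconds (vectorized).
#' @param tau_c Correlation time in seconds (vectorized).
#' @return Contrast K, dimensionless, in (0, 1].
#' @export
#' @examples
#' contrast_model(20e-3, 2e-3)   # long exposure: strong blurring, low K
#' contrast_model(0.5e-3, 2e-3)  # short exposure: K near 1
contrast_model <- function(exposure_time, tau_c) {
  if (any(exposure_time <= 0) || any(tau_c <= 0))
    stop_especkle("exposure_time and tau_c must be positive",
                  "especkle_invalid_config")
  x <- 2 * exposure_time / tau_c
  sqrt((1 - exp(-x)) / x)
}

# Low-pass spectral mask producing a speckle grain of ~2 px (field
# bandwidth 0.25 cycles/px), normalized so E|field|^2 = 1 under R's
# unnormalized inverse FFT.
speckle_mask <- function(nr, nc, grain_freq = 0.25) {
  f <- radial_freq(nr, nc)
  m <- (f <= grain_freq) * 1
  m / sqrt(sum(m^2))
}

# One fresh fully developed complex speckle field (unit mean intensity).
draw_field_spectrum <- function(mask) {
  n <- length(mask)
  w <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)),
              nrow = nrow(mask)) / sqrt(2)
  mask * w
}

# Smooth occlusion gate: ~1 inside [t0, t1], ~0 outside, logistic edges.
occlusion_gate <- function(t, window, edge = 0.1) {
  if (is.null(window)) return(rep(0, length(t)))
  plogis((t - window[1]) / edge) * (1 - plogis((t - window[2]) / edge))
}

# Chromophore delta trajectory (mM, relative units): logistic rise over the
# occlusion, exponential recovery after release.
chromophore_trajectory <- function(t, physiology, rise = 0.5, fall = 5) {
  w <- physiology$occlusion_window
  if (is.null(w)) return(cbind(d_hbo2 = rep(0, length(t)),
                               d_hb = rep(0, length(t))))
  target <- switch(physiology$occlusion_mode,
                   arterial = c(-0.3, 0.1),
                   arteriovenous = c(0.3, 0.1))
  base <- plogis((pmin(t, w[2]) - w[1]) / rise)
  decay <- exp(-pmax(t - w[2], 0) / fall)
  shape <- base * decay
  cbind(d_hbo2 = target[1] * shape, d_hb = target[2] * shape)
}

# Instantaneous speckle correlation time (s): cardiac and respiratory
# sinusoids modulate 1/tau_c; occlusion multiplies tau_c (slower flow).
tau_c_at <- function(t, physiology) {
  f_c <- physiology$heart_rate / 60
  f_r <- physiology$respiratory_rate / 60
  mod <- 1 +
    physiology$cardiac_modulation_depth * sin(2 * pi * f_c * t) +
    physiology$respiratory_modulation_depth * sin(2 * pi * f_r * t)
  gate <- occlusion_gate(t, physiology$occlusion_window)
  physiology$baseline_correlation_time *
    (1 + (physiology$occlusion_tau_factor - 1) * gate) / mod
}

#' Simulate a dual-wavelength endoscopic speckle acquisition
#'
#' Generates raw speckle image stacks with known physiological ground truth,
#' emulating intra-operative recordings: fully developed speckle whose local
#' contrast follows [contrast_model()] through sub-exposure temporal
#' decorrelation of a low-pass-filtered complex Gaussian field (10
#' integration steps per exposure); sinusoidal cardiac and respiratory
#' modulation of the correlation time; a Beer-Lambert forward model tying
#' per-wavelength mean intensity to the chromophore trajectory; Poisson shot
#' noise plus Gaussian read noise quantized to the detector bit depth; and
#' jittered timestamps.
#'
#' During an `occlusion_window` the correlation time rises (flow stops, so
#' contrast steps up) and chromophores follow the occlusion mode: arterial
#' occlusion depletes oxy-hemoglobin; arteriovenous occlusion pools venous
#' blood, raising oxy- and total hemoglobin.
#'
#' @param config An [acquisition_config()].
#' @param physiology A [physiology_params()].
#' @param seed Integer seed; identical inputs and seed reproduce the stacks
#'   bit-for-bit. The caller's RNG state is preserved.
#' @return A list of class `especkle_simulation` with elements `stacks`
#'   (named list of [speckle_stack()], one per wavelength) and
#'   `ground_truth` (hidden parameters: per-frame `tau_c`, chromophore
#'   deltas, timestamps, the physiology and the seed).
#' @export
simulate_stack <- function(config, physiology, seed) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(physiology, "physiology_params"))
  nf <- config$frame_count
  fps <- config$nominal_frame_rate
  duration <- nf / fps
  if (!is.null(physiology$occlusion_window) &&
      physiology$occlusion_window[2] > duration + 1e-9)
    stop_especkle("occlusion_window extends beyond the recording duration",
                  "especkle_invalid_physiology")

  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  mask <- speckle_mask(nr, nc)
  n_sub <- 10L
  delta <- config$exposure_time / n_sub
  maxdn <- 2^config$bit_depth - 1
  etab <- extinction_table()

  with_seed(seed, {
    stacks <- list()
    gt_tau <- list(); gt_chrom <- list(); gt_ts <- list()
    for (wi in seq_along(config$wavelengths)) {
      wl <- config$wavelengths[wi]
      offset <- if (config$interleaved) (wi - 1) / (length(config$wavelengths) * fps) else 0
      nominal <- (seq_len(nf) - 1) / fps + offset
      jit <- rnorm(nf, sd = config$timestamp_jitter_sd)
      jit <- pmin(pmax(jit, -0.45 / fps), 0.45 / fps)
      ts <- nominal + jit
      for (k in seq_len(nf)[-1])
        if (ts[k] <= ts[k - 1]) ts[k] <- ts[k - 1] + 1e-6

      chrom <- chromophore_trajectory(ts, physiology)
      eps <- extinction_row(etab, wl)
      od <- etab$pathlength_factor *
        (eps[1] * chrom[, "d_hbo2"] + eps[2] * chrom[, "d_hb"])
      mean_dn <- config$mean_intensity * exp(-od)
      tau_frames <- tau_c_at(ts, physiology)

      frames <- array(0L, dim = c(nf, nr, nc))
      spec <- draw_field_spectrum(mask)
      t_prev <- ts[1] - delta
      for (fi in seq_len(nf)) {
        tau <- tau_frames[fi]
        acc <- matrix(0, nr, nc)
        for (si in seq_len(n_sub)) {
          t_k <- ts[fi] + (si - 1) * delta
          rho <- exp(-(t_k - t_prev) / tau)
          spec <- rho * spec + sqrt(1 - rho^2) * draw_field_spectrum(mask)
          field <- fft(spec, inverse = TRUE)
          acc <- acc + Re(field)^2 + Im(field)^2
          t_prev <- t_k
        }
        img <- acc / n_sub * mean_dn[fi]
        if (config$shot_noise) img[] <- rpois(length(img), lambda = img)
        if (config$read_noise_sd > 0)
          img <- img + rnorm(length(img), sd = config$read_noise_sd)
        frames[fi, , ] <- pmin(pmax(round(img), 0), maxdn)
      }
      storage.mode(frames) <- "integer"
      key <- as.character(wl)
      stacks[[key]] <- speckle_stack(
        frames, ts, wl, config$exposure_time, config$bit_depth,
        metadata = list(simulated = TRUE, seed = seed,
                        nominal_frame_rate = fps,
                        interleaved = config$interleaved))
      gt_tau[[key]] <- tau_frames
      gt_chrom[[key]] <- chrom
      gt_ts[[key]] <- ts
    }
    structure(list(
      stacks = stacks,
      ground_truth = list(params = physiology,
                          config = config,
                          per_frame_tau_c = gt_tau,
                          per_frame_chromophores = gt_chrom,
                          timestamps = gt_ts,
                          seed = seed)),
      class = "especkle_simulation")
  })
}

#' Hexagonal fiber-bundle transmission pattern
#'
#' The honeycomb pattern a leached fiber image guide imprints on endoscopic
#' frames: a static hexagonal lattice built from three cosine gratings at
#' 0, 60 and 120 degrees, each of spatial frequency `1/core_spacing`
#' cycles/px, mapped to a transmission in `[1 - modulation_depth, 1]`.
#'
#' @param shape `c(rows, cols)` pixels.
#' @param core_spacing Fiber core spacing in pixels, `>= 3`.
#' @param modulation_depth Transmission modulation depth in `(0, 1]`.
#' @return A `rows x cols` transmission matrix.
#' @export
fiber_bundle_pattern <- function(shape, core_spacing, modulation_depth) {
  if (core_spacing < 3)
    stop_especkle("core_spacing must be >= 3 px", "especkle_invalid_pattern")
  if (modulation_depth <= 0 || modulation_depth > 1)
    stop_especkle("modulation_depth must be in (0, 1]",
                  "especkle_invalid_pattern")
  nr <- shape[1]; nc <- shape[2]
  y <- matrix(0:(nr - 1), nr, nc)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  f <- 2 * pi / core_spacing
  ang <- c(0, pi / 3, 2 * pi / 3)
  g <- matrix(0, nr, nc)
  for (a in ang) g <- g + cos(f * (cos(a) * x + sin(a) * y))
  g <- g / 3                       # in [-0.5, 1]
  1 - modulation_depth * (1 - (g + 0.5) / 1.5)
}

#' Overlay a static fiber-bundle pattern onto a stack
#'
#' Multiplies every frame by the same hexagonal transmission pattern
#' (the pattern is a property of the imaging bundle, hence frame-invariant)
#' and re-quantizes to the detector bit depth.
#'
#' @param stack A [speckle_stack()].
#' @param core_spacing Fiber core spacing in pixels (default 8).
#' @param modulation_depth Transmission modulation depth in `(0, 1]`.
#' @return A [speckle_stack()] with the pattern applied; metadata records
#'   the spacing and depth.
#' @export
overlay_fiber_pattern <- function(stack, core_spacing = 8,
                                  modulation_depth = 0.4) {
  stopifnot(inherits(stack, "speckle_stack"))
  d <- dim(stack$frames)
  pat <- fiber_bundle_pattern(d[2:3], core_spacing, modulation_depth)
  frames <- stack$frames
  for (i in seq_len(d[1]))
    frames[i, , ] <- round(stack$frames[i, , ] * pat)
  storage.mode(frames) <- "integer"
  md <- stack$metadata
  md$fiber_core_spacing <- core_spacing
  md$fiber_modulation_depth <- modulation_depth
  speckle_stack(frames, stack$timestamps, stack$wavelength,
                stack$exposure_time, stack$bit_depth, md)
}
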