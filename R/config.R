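#' Acquisition configuration for the synthetic speckle simulator
#'
#' Describes one simulated endoscopic acquisition: camera exposure, nominal
#' per-wavelength frame rate, illumination wavelengths, frame geometry and
#' the detector model. The documented exposure presets are 500 us, 1 ms,
#' 10 ms and 20 ms (the settings used intra-operatively); any positive
#' exposure not exceeding the frame period is accepted.
#'
#' @param exposure_time Camera exposure in seconds; must satisfy
#'   `0 < exposure_time <= 1/nominal_frame_rate`.
#' @param nominal_frame_rate Frames per second *per wavelength*.
#' @param frame_count Number of frames per wavelength.
#' @param wavelengths Illumination wavelengths in nm (default `c(660, 830)`;
#'   subset of 660/830, the red/near-infrared laser diode pair).
#' @param frame_shape `c(rows, cols)` in pixels, each at least 16 so the
#'   speckle grain (about 2 px) is resolved.
#' @param bit_depth Detector bit depth (default 12; intensities are digitized
#'   to `[0, 2^bit_depth - 1]` DN).
#' @param interleaved If `TRUE`, the two wavelengths alternate frame-by-frame
#'   (laser switching synchronized with the camera) and the 830 nm timestamps
#'   are offset by half a frame period.
#' @param timestamp_jitter_sd Standard deviation (seconds) of Gaussian jitter
#'   added to nominal frame times; default 5% of the frame period, reflecting
#'   measured-vs-set frame-rate discrepancy. Jitter is clipped at 45% of the
#'   period so timestamps stay strictly increasing.
#' @param mean_intensity Baseline mean detected intensity in DN (default
#'   500, leaving 8x headroom below the 12-bit ceiling so the exponential
#'   speckle intensity tail is not clipped).
#' @param read_noise_sd Gaussian read noise standard deviation in DN
#'   (default 2).
#' @param shot_noise Apply Poisson shot noise (default `TRUE`).
#' @return An object of class `acquisition_config`.
#' @seealso [simulate_stack()], [physiology_params()]
#' @export
acquisition_config <- function(exposure_time,
                               nominal_frame_rate,
                               frame_count,
                               wavelengths = c(660, 830),
                               frame_shape = c(64L, 64L),
                               bit_depth = 12L,
                               interleaved = FALSE,
                               timestamp_jitter_sd = NULL,
                               mean_intensity = 500,
                               read_noise_sd = 2,
                               shot_noise = TRUE) {
  if (!is.numeric(exposure_time) || length(exposure_time) != 1L ||
      exposure_time <= 0)
    stop_especkle("exposure_time must be a positive scalar (seconds)",
                  "especkle_invalid_config")
  if (!is.numeric(nominal_frame_rate) || nominal_frame_rate <= 0)
    stop_especkle("nominal_frame_rate must be positive",
                  "especkle_invalid_config")
  if (exposure_time > 1 / nominal_frame_rate + 1e-12)
    stop_especkle("exposure_time exceeds the frame period 1/nominal_frame_rate",
                  "especkle_invalid_config")
  frame_count <- as.integer(frame_count)
  if (frame_count < 1L)
    stop_especkle("frame_count must be >= 1", "especkle_invalid_config")
  if (!all(wavelengths %in% c(660, 830)))
    stop_especkle("wavelengths must be a subset of c(660, 830)",
                  "especkle_invalid_config")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 16L))
    stop_especkle("frame_shape must be c(rows, cols) with both >= 16",
                  "especkle_invalid_config")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 8L || bit_depth > 16L)
    stop_especkle("bit_depth must be in [8, 16]", "especkle_invalid_config")
  if (interleaved && length(wavelengths) != 2L)
    stop_especkle("interleaved acquisition needs exactly two wavelengths",
                  "especkle_invalid_config")
  jit <- timestamp_jitter_sd %||% (0.05 / nominal_frame_rate)
  if (jit < 0) stop_especkle("timestamp_jitter_sd must be >= 0",
                             "especkle_invalid_config")
  if (mean_intensity <= 0 || mean_intensity > 2^bit_depth - 1)
    stop_especkle("mean_intensity must lie in (0, 2^bit_depth - 1]",
                  "especkle_invalid_config")
  structure(list(exposure_time = exposure_time,
                 nominal_frame_rate = nominal_frame_rate,
                 frame_count = frame_count,
                 wavelengths = wavelengths,
                 frame_shape = frame_shape,
                 bit_depth = bit_depth,
                 interleaved = interleaved,
                 timestamp_jitter_sd = jit,
                 mean_intensity = mean_intensity,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "acquisition_config")
}

#' Physiological ground-truth parameters for the simulator
#'
#' The simulator modulates the speckle correlation time `tau_c` sinusoidally
#' at the cardiac and respiratory frequencies and, inside an optional
#' occlusion window, multiplies it by `occlusion_tau_factor` (flow slows, so
#' speckle decorrelates more slowly and contrast rises). Chromophore
#' concentration changes follow the occlusion mode: `"arterial"` inflow
#' block depletes oxy-hemoglobin; `"arteriovenous"` (artery and adjacent
#' vein clamped together) pools venous blood so both oxy-hemoglobin and
#' total hemoglobin rise.
#'
#' @param heart_rate Beats per minute, in `[30, 300]`. The rabbit range is
#'   130-220 bpm; sheep about 109 bpm.
#' @param respiratory_rate Breaths per minute, in `[5, 80]` (rabbit 30-60).
#' @param cardiac_modulation_depth,respiratory_modulation_depth Fractional
#'   sinusoidal modulation of `1/tau_c` (0 disables); their sum must stay
#'   below 0.95 so `tau_c` remains positive.
#' @param baseline_correlation_time Baseline `tau_c` in seconds (default
#'   2 ms, a physiological perfusion scale commensurate with the exposure
#'   presets).
#' @param occlusion_window Optional `c(t_start, t_end)` seconds.
#' @param occlusion_mode `"arterial"` or `"arteriovenous"`.
#' @param occlusion_tau_factor Multiplicative increase of `tau_c` during the
#'   occlusion (default 6).
#' @param hbo2_baseline,hb_baseline Baseline chromophore concentrations in
#'   relative mM units (metadata; deltas are reported against the recording
#'   start).
#' @return An object of class `physiology_params`.
#' @export
physiology_params <- function(heart_rate = 180,
                              respiratory_rate = 36,
                              cardiac_modulation_depth = 0.4,
                              respiratory_modulation_depth = 0.3,
                              baseline_correlation_time = 2e-3,
                              occlusion_window = NULL,
                              occlusion_mode = c("arterial", "arteriovenous"),
                              occlusion_tau_factor = 6,
                              hbo2_baseline = 0,
                              hb_baseline = 0) {
  occlusion_mode <- match.arg(occlusion_mode)
  if (heart_rate < 30 || heart_rate > 300)
    stop_especkle("heart_rate must be within [30, 300] bpm",
                  "especkle_invalid_physiology")
  if (respiratory_rate < 5 || respiratory_rate > 80)
    stop_especkle("respiratory_rate must be within [5, 80] breaths/min",
                  "especkle_invalid_physiology")
  if (cardiac_modulation_depth < 0 || respiratory_modulation_depth < 0 ||
      cardiac_modulation_depth + respiratory_modulation_depth >= 0.95)
    stop_especkle("modulation depths must be >= 0 and sum to < 0.95",
                  "especkle_invalid_physiology")
  if (baseline_correlation_time <= 0)
    stop_especkle("baseline_correlation_time must be positive",
                  "especkle_invalid_physiology")
  if (!is.null(occlusion_window)) {
    if (length(occlusion_window) != 2L || occlusion_window[1] < 0 ||
        occlusion_window[1] >= occlusion_window[2])
      stop_especkle("occlusion_window must be c(t_start, t_end) with 0 <= t_start < t_end",
                    "especkle_invalid_physiology")
  }
  if (occlusion_tau_factor <= 1)
    stop_especkle("occlusion_tau_factor must exceed 1 (flow slows under occlusion)",
                  "especkle_invalid_physiology")
  structure(list(heart_rate = heart_rate,
                 respiratory_rate = respiratory_rate,
                 cardiac_modulation_depth = cardiac_modulation_depth,
                 respiratory_modulation_depth = respiratory_modulation_depth,
                 baseline_correlation_time = baseline_correlation_time,
                 occlusion_window = occlusion_window,
                 occlusion_mode = occlusion_mode,
                 occlusion_tau_factor = occlusion_tau_factor,
                 hbo2_baseline = hbo2_baseline,
                 hb_baseline = hb_baseline),
            class = "physiology_params")
}
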