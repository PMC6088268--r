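#' Construct a speckle image stack
#'
#' A time-ordered stack of raw speckle frames at one illumination wavelength,
#' with per-frame acquisition timestamps. Frames are stored as a
#' `time x rows x cols` array of detector numbers (DN).
#'
#' @param frames 3-D numeric array `(time, rows, cols)`, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param timestamps Strictly increasing acquisition times in seconds, one
#'   per frame.
#' @param wavelength Illumination wavelength in nm.
#' @param exposure_time Camera exposure in seconds (may be `NA` for stacks
#'   read without metadata).
#' @param bit_depth Detector bit depth (default 12).
#' @param metadata Free-form provenance list.
#' @return An object of class `speckle_stack`.
#' @export
speckle_stack <- function(frames, timestamps, wavelength,
                          exposure_time = NA_real_, bit_depth = 12L,
                          metadata = list()) {
  if (length(dim(frames)) != 3L)
    stop_especkle("frames must be a 3-D array (time, rows, cols)",
                  "especkle_invalid_stack")
  nf <- dim(frames)[1]
  if (length(timestamps) != nf)
    stop_especkle(sprintf("timestamp count (%d) != frame count (%d)",
                          length(timestamps), nf),
                  "especkle_invalid_stack")
  if (nf > 1L && any(diff(timestamps) <= 0))
    stop_especkle("timestamps must be strictly increasing",
                  "especkle_invalid_stack")
  maxdn <- 2^bit_depth - 1
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > maxdn)
    stop_especkle(sprintf("intensities must lie in [0, %d]", maxdn),
                  "especkle_invalid_stack")
  structure(list(frames = frames,
                 timestamps = as.numeric(timestamps),
                 wavelength = wavelength,
                 exposure_time = exposure_time,
                 bit_depth = as.integer(bit_depth),
                 metadata = metadata),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d frames of %dx%d px at %s nm\n",
              d[1], d[2], d[3], format(x$wavelength)))
  cat(sprintf("  exposure %s s, %d-bit, t = [%.3f, %.3f] s\n",
              format(x$exposure_time), x$bit_depth,
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [speckle_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Extract one frame from a stack
#' @param stack A [speckle_stack()].
#' @param i Frame index (1-based).
#' @return A `rows x cols` numeric matrix.
#' @export
get_frame <- function(stack, i) {
  stack$frames[i, , , drop = TRUE]
}

#' Construct a contrast time series
#'
#' The region-averaged speckle contrast K plotted against acquisition time:
#' the signal on which physiological rate extraction and occlusion detection
#' operate.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param k Contrast values, same length as `t`.
#' @param wavelength Wavelength in nm (optional).
#' @param roi 0-based half-open ROI bounds `c(r0, r1, c0, c1)` (optional).
#' @param native_rate Mean sampling rate (samples/s) of the *original*
#'   acquisition; carried through resampling so the usable Nyquist limit is
#'   not inflated by interpolation.
#' @param uniform Logical, `TRUE` when the grid is uniform.
#' @return A data frame of class `contrast_series` with columns `t`, `k`.
#' @export
contrast_series <- function(t, k, wavelength = NA_real_, roi = NULL,
                            native_rate = NULL, uniform = NA) {
  if (length(t) != length(k))
    stop_especkle("t and k must have equal length", "especkle_invalid_series")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_especkle("timestamps must be strictly increasing",
                  "especkle_invalid_series")
  nr <- native_rate %||%
    if (length(t) > 1L) (length(t) - 1) / (t[length(t)] - t[1]) else NA_real_
  if (is.na(uniform))
    uniform <- length(t) > 2L &&
      max(abs(diff(t) - mean(diff(t)))) <= 1e-9 * mean(diff(t))
  structure(data.frame(t = as.numeric(t), k = as.numeric(k)),
            wavelength = wavelength, roi = roi,
            native_rate = nr, uniform = isTRUE(uniform),
            class = c("contrast_series", "data.frame"))
}

series_dt <- function(series) {
  t <- series$t
  if (length(t) < 2L) return(NA_real_)
  mean(diff(t))
}
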