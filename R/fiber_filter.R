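#' Specification of the 2-D Butterworth low-pass filter
#'
#' @param cutoff Cutoff spatial frequency in cycles/pixel, `0 < cutoff < 0.5`
#'   (below Nyquist).
#' @param order Filter order, integer `>= 1` (default 4: steep enough to
#'   separate the bundle carrier from perfusion content without ringing).
#' @return An object of class `fiber_filter_spec`.
#' @export
fiber_filter_spec <- function(cutoff, order = 4L) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 0.5)
    stop_especkle("cutoff must satisfy 0 < cutoff < 0.5 cycles/px",
                  "especkle_invalid_filter")
  order <- as.integer(order)
  if (order < 1L)
    stop_especkle("order must be >= 1", "especkle_invalid_filter")
  structure(list(cutoff = cutoff, order = order, domain = "2D-frequency"),
            class = "fiber_filter_spec")
}

butterworth2d <- function(nr, nc, cutoff, order) {
  f <- radial_freq(nr, nc)
  1 / (1 + (f / cutoff)^(2 * order))
}

#' Remove the fiber-bundle honeycomb pattern from a frame
#'
#' Applies a radially symmetric 2-D Butterworth low-pass transfer function
#' `H(f) = 1 / (1 + (f/cutoff)^(2 order))` in the frequency domain. The DC
#' gain is exactly 1, so the mean intensity is preserved; the periodic
#' bundle carrier (typically 0.08-0.15 cycles/px) is strongly attenuated.
#'
#' @param frame 2-D intensity matrix, both dimensions `>= 16`.
#' @param spec A [fiber_filter_spec()].
#' @return A real-valued matrix, same shape as `frame`.
#' @export
remove_fiber_pattern <- function(frame, spec) {
  stopifnot(inherits(spec, "fiber_filter_spec"))
  if (!is.matrix(frame) || nrow(frame) < 16 || ncol(frame) < 16)
    stop_especkle("frame must be a matrix with both dimensions >= 16",
                  "especkle_invalid_frame")
  h <- butterworth2d(nrow(frame), ncol(frame), spec$cutoff, spec$order)
  Re(fft(fft(frame) * h, inverse = TRUE)) / length(frame)
}

#' Estimate the fiber-bundle carrier frequency of a frame
#'
#' Finds the dominant non-DC radial spatial frequency: the power spectrum is
#' averaged over annuli of width `1/min(dim)` cycles/px across the search
#' band (0.03-0.35 cycles/px) and the peak annulus must stand at least 6 dB
#' above the median annulus power; the returned value is the radial
#' frequency of the strongest spectral pixel inside that annulus. Use the
#' time-averaged frame of a stack for a clean estimate (temporal averaging
#' suppresses speckle but not the static pattern).
#'
#' @param frame 2-D intensity matrix.
#' @param f_range Radial search band in cycles/px (default `c(0.03, 0.35)`).
#' @return The carrier frequency in cycles/px, or `NA_real_` when no peak
#'   rises 6 dB above the radial-spectrum median ("no pattern detected").
#' @export
estimate_core_spacing <- function(frame, f_range = c(0.03, 0.35)) {
  if (!is.matrix(frame))
    stop_especkle("frame must be a 2-D matrix", "especkle_invalid_frame")
  p <- Mod(fft(frame - mean(frame)))^2
  f <- radial_freq(nrow(frame), ncol(frame))
  width <- 1 / min(dim(frame))
  sel <- f >= f_range[1] & f <= f_range[2]
  bin <- floor(f[sel] / width)
  prof <- tapply(p[sel], bin, mean)
  if (length(prof) < 4L) return(NA_real_)
  peak <- which.max(prof)
  if (prof[peak] < 4 * median(prof)) return(NA_real_)   # < 6 dB: no pattern
  peak_bin <- as.integer(names(prof)[peak])
  inb <- sel & floor(f / width) == peak_bin
  f[inb][which.max(p[inb])]
}

#' Auto-configure the bundle filter from a stack
#'
#' Estimates the bundle carrier frequency on the time-averaged frame and
#' returns a [fiber_filter_spec()] with cutoff at half that frequency, or
#' `NULL` when no pattern is detected (filtering can then be skipped).
#'
#' @param stack A [speckle_stack()].
#' @param order Butterworth order (default 4).
#' @return A [fiber_filter_spec()] or `NULL`.
#' @export
auto_filter_spec <- function(stack, order = 4L) {
  stopifnot(inherits(stack, "speckle_stack"))
  avg <- apply(stack$frames, c(2, 3), mean)
  f0 <- estimate_core_spacing(avg)
  if (is.na(f0)) return(NULL)
  fiber_filter_spec(cutoff = f0 / 2, order = order)
}

#' Filter every frame of a stack
#'
#' Applies [remove_fiber_pattern()] frame-by-frame (filtering acts on raw
#' frames before contrast computation). Filtered intensities are clamped to
#' the valid detector range; frames become floating point.
#'
#' @param stack A [speckle_stack()].
#' @param spec A [fiber_filter_spec()].
#' @return A filtered [speckle_stack()]; metadata records the filter.
#' @export
filter_stack <- function(stack, spec) {
  stopifnot(inherits(stack, "speckle_stack"),
            inherits(spec, "fiber_filter_spec"))
  d <- dim(stack$frames)
  h <- butterworth2d(d[2], d[3], spec$cutoff, spec$order)
  frames <- array(0, dim = d)
  maxdn <- 2^stack$bit_depth - 1
  for (i in seq_len(d[1])) {
    fr <- Re(fft(fft(stack$frames[i, , , drop = TRUE]) * h,
                 inverse = TRUE)) / (d[2] * d[3])
    frames[i, , ] <- pmin(pmax(fr, 0), maxdn)
  }
  md <- stack$metadata
  md$fiber_filter <- list(cutoff = spec$cutoff, order = spec$order)
  speckle_stack(frames, stack$timestamps, stack$wavelength,
                stack$exposure_time, stack$bit_depth, md)
}
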