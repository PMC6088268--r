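#' Spatial speckle-contrast map of a single frame
#'
#' The LASCA estimator: for every pixel, the ratio of the sample standard
#' deviation to the mean of the intensities inside a centered
#' `window_size x window_size` neighborhood, with reflective (edge-inclusive)
#' border padding so the map aligns pixel-for-pixel with the frame. Low K
#' marks fast flow (speckle blurred within the exposure); K near 1 marks
#' static, fully developed speckle.
#'
#' @param frame 2-D numeric matrix of intensities (DN).
#' @param window_size Odd integer window edge, `>= 3` (default 7, the usual
#'   balance between spatial resolution and estimator variance; 5 and 9 are
#'   common alternatives).
#' @return A matrix of K values, same shape as `frame`, with attributes
#'   `window_size`. K is `NaN` only where the window mean is 0 (all-dark
#'   window).
#' @export
#' @examples
#' contrast_map(matrix(1:81, 9, 9), window_size = 3)[5, 5]
contrast_map <- function(frame, window_size = 7L) {
  if (!is.matrix(frame))
    stop_especkle("frame must be a 2-D matrix", "especkle_invalid_frame")
  w <- as.integer(window_size)
  if (w %% 2L == 0L || w < 3L)
    stop_especkle("window_size must be an odd integer >= 3",
                  "especkle_invalid_window")
  if (nrow(frame) < w || ncol(frame) < w)
    stop_especkle("frame smaller than the contrast window",
                  "especkle_invalid_frame")
  if (any(frame < 0))
    stop_especkle("negative intensities are not valid speckle data",
                  "especkle_invalid_frame")
  r <- (w - 1L) %/% 2L
  n <- w * w
  xp <- frame[reflect_idx(nrow(frame), r), reflect_idx(ncol(frame), r),
              drop = FALSE]
  m <- box_sum_padded(xp, w) / n
  # center on the global mean before squaring: kills catastrophic
  # cancellation (uniform frames give exactly zero variance)
  mu <- mean(frame)
  yp <- xp - mu
  s1 <- box_sum_padded(yp, w)
  s2 <- box_sum_padded(yp * yp, w)
  v <- (s2 - s1 * s1 / n) / (n - 1)
  v[v < 0] <- 0
  k <- sqrt(v) / m
  k[m == 0] <- NaN
  structure(k, window_size = w)
}

#' ROI-averaged contrast time series from a stack
#'
#' For each frame, computes the spatial contrast map and averages K over the
#' region of interest (NaN pixels excluded), yielding the contrast-vs-time
#' signal from which physiological rates and occlusion events are extracted.
#'
#' @param stack A [speckle_stack()].
#' @param roi 0-based half-open bounds `c(r0, r1, c0, c1)`; `NULL` (default)
#'   uses the full frame.
#' @param window_size Odd contrast window (default 7).
#' @return A [contrast_series()] with the stack's timestamps. A frame whose
#'   ROI is entirely NaN yields an NA sample (with a warning); downstream
#'   stages drop NA samples.
#' @export
roi_contrast_series <- function(stack, roi = NULL, window_size = 7L) {
  stopifnot(inherits(stack, "speckle_stack"))
  d <- dim(stack$frames)
  roi <- check_roi(roi %||% c(0, d[2], 0, d[3]), d[2], d[3])
  rows <- (roi[1] + 1):roi[2]
  cols <- (roi[3] + 1):roi[4]
  k <- vapply(seq_len(d[1]), function(i) {
    km <- contrast_map(stack$frames[i, , , drop = TRUE], window_size)
    mean(km[rows, cols], na.rm = TRUE)
  }, numeric(1))
  k[is.nan(k)] <- NA_real_
  if (anyNA(k))
    warning(sprintf("%d frame(s) had an entirely dark ROI (NA contrast)",
                    sum(is.na(k))))
  contrast_series(stack$timestamps, k, wavelength = stack$wavelength,
                  roi = roi,
                  native_rate = stack$metadata$nominal_frame_rate %||% NULL)
}
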