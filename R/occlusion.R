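#' Detect vascular occlusion onset and release in a contrast series
#'
#' Clamping a supplying vessel stops flow, so speckle decorrelation slows
#' and the region-averaged contrast steps *up*; release drops it back. The
#' detector suppresses respiratory spikes with a moving median, then runs an
#' exhaustive two-change-point search minimizing the residual sum of squares
#' of a three-segment piecewise-constant fit (baseline / occluded /
#' released). A call is emitted only when the middle segment exceeds the
#' baseline mean by at least `min_shift_sd` baseline standard deviations for
#' at least `min_duration` seconds. If the third segment does not drop back
#' below the occluded level by the same margin, the release is reported as
#' absent (`NA`): the recording ended while still occluded.
#'
#' @param series A [contrast_series()] with at least 20 samples and total
#'   duration at least `3 * min_duration`. NA gaps above 20% are rejected.
#' @param min_shift_sd Minimum level shift in baseline standard deviations
#'   (default 3).
#' @param min_duration Minimum occluded duration in seconds (default 5).
#' @param spike_period Expected respiratory spike period in seconds; the
#'   moving-median width is 3 x this value when supplied, else 5 s.
#' @return An object of class `occlusion_call` (list with `onset`,
#'   `release`, `baseline_level`, `occluded_level`, `released_level`,
#'   `effect_size`) or `NULL` when no acceptable shift exists. Boundary
#'   times are the midpoints between the bracketing samples.
#' @export
detect_occlusion <- function(series, min_shift_sd = 3, min_duration = 5,
                             spike_period = NULL) {
  stopifnot(inherits(series, "contrast_series"))
  k <- series$k; t <- series$t
  if (mean(is.na(k)) > 0.2)
    stop_especkle("more than 20% NA samples", "especkle_invalid_series")
  ok <- !is.na(k); k <- k[ok]; t <- t[ok]
  n <- length(k)
  if (n < 20L)
    stop_especkle("occlusion detection needs at least 20 samples",
                  "especkle_too_few_samples")
  dt <- mean(diff(t))
  if (t[n] - t[1] < 3 * min_duration)
    stop_especkle("series shorter than 3 x min_duration",
                  "especkle_too_few_samples")

  width_s <- if (!is.null(spike_period)) 3 * spike_period else 5
  width <- max(3L, round(width_s / dt))
  if (width %% 2L == 0L) width <- width + 1L
  ks <- if (width < n) runmed(k, width, endrule = "median") else k

  # three-segment piecewise-constant fit by exhaustive (i, j) search;
  # prefix sums make each candidate O(1)
  cs <- cumsum(ks); cs2 <- cumsum(ks^2)
  seg_sse <- function(a, b) {  # samples a..b
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    q <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    q - s^2 / (b - a + 1)
  }
  min_mid <- max(3L, ceiling(min_duration / dt))
  best2 <- NULL; best2_sse <- Inf
  for (i in 2:(n - min_mid - 1L)) {
    sse1 <- seg_sse(1L, i)
    jmax <- n - 2L
    jmin <- i + min_mid
    if (jmin > jmax) next
    for (j in jmin:jmax) {
      sse <- sse1 + seg_sse(i + 1L, j) + seg_sse(j + 1L, n)
      if (sse < best2_sse) { best2_sse <- sse; best2 <- c(i, j) }
    }
  }
  best1 <- NULL; best1_sse <- Inf
  for (i in 2:(n - min_mid)) {
    sse <- seg_sse(1L, i) + seg_sse(i + 1L, n)
    if (sse < best1_sse) { best1_sse <- sse; best1 <- i }
  }
  if (is.null(best1) && is.null(best2)) return(NULL)
  eval_fit <- function(i, j) {
    m1 <- mean(ks[1:i]); m2 <- mean(ks[(i + 1):j])
    sd1 <- max(sd(ks[1:i]), .Machine$double.eps)
    list(i = i, j = j, m1 = m1, m2 = m2, sd1 = sd1,
         valid = (m2 - m1) >= min_shift_sd * sd1)
  }
  # prefer the full baseline/occluded/released fit; an open-ended occlusion
  # (recording stops while still clamped) falls back to a single step up
  fit <- NULL; two <- FALSE
  if (!is.null(best2)) {
    f2 <- eval_fit(best2[1], best2[2])
    if (f2$valid) { fit <- f2; two <- TRUE }
  }
  if (is.null(fit) && !is.null(best1)) {
    f1 <- eval_fit(best1, n)
    if (f1$valid) fit <- f1
  }
  if (is.null(fit)) return(NULL)
  i <- fit$i; j <- fit$j
  m3 <- if (two) mean(ks[(j + 1):n]) else NA_real_
  release <- if (two && fit$m2 - m3 >= min_shift_sd * fit$sd1)
    (t[j] + t[j + 1]) / 2 else NA_real_
  structure(list(onset = (t[i] + t[i + 1]) / 2,
                 release = release,
                 baseline_level = fit$m1,
                 occluded_level = fit$m2,
                 released_level = m3,
                 effect_size = (fit$m2 - fit$m1) / fit$sd1),
            class = "occlusion_call")
}

#' @export
print.occlusion_call <- function(x, ...) {
  cat(sprintf("<occlusion_call> onset %.2f s, release %s\n", x$onset,
              if (is.na(x$release)) "absent" else sprintf("%.2f s", x$release)))
  cat(sprintf("  contrast %.3f -> %.3f (effect size %.1f baseline SD)\n",
              x$baseline_level, x$occluded_level, x$effect_size))
  invisible(x)
}
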