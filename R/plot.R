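#' Plot a contrast time series
#'
#' @param x A [contrast_series()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contrast_series <- function(x, ...) {
  plot(x$t, x$k, type = "l", xlab = "time (s)", ylab = "speckle contrast K",
       main = "ROI-averaged contrast", ...)
  invisible(x)
}

#' Plot a power spectrum
#'
#' DC bin omitted; peaks in the respiratory (0.1-1 Hz) and cardiac (1-4 Hz)
#' bands carry the physiological rates.
#'
#' @param x A [power_spectrum()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.power_spectrum <- function(x, ...) {
  sel <- x$freq > 0
  plot(x$freq[sel], x$power[sel], type = "l",
       xlab = "frequency (Hz)", ylab = "power (a.u.)",
       main = "Contrast power spectrum", ...)
  invisible(x)
}

#' Render a contrast (or ratio) map
#'
#' Low contrast (fast flow) renders dark blue, high contrast (slow/static)
#' light; NaN pixels are dropped.
#'
#' @param map Matrix from [contrast_map()] or [oxygenation_map()].
#' @param main Title.
#' @export
plot_contrast_map <- function(map, main = "Speckle contrast map") {
  m <- t(map[nrow(map):1, , drop = FALSE])
  image(m, col = hcl.colors(64, "Blues 3", rev = TRUE), axes = FALSE,
        main = main, useRaster = TRUE)
  invisible(map)
}
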