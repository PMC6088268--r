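# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_especkle <- function(msg, class) {
  stop(structure(class = c(class, "especkle_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# FFT bin frequencies in cycles per sample for an n-point transform,
# in R's fft output order (0, 1/n, ..., -1/n).
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Matrix of radial spatial frequency (cycles/px) for a nr x nc frame.
radial_freq <- function(nr, nc) {
  fy <- fft_freqs(nr)
  fx <- fft_freqs(nc)
  sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
}

# Edge-inclusive (symmetric) reflective padding indices for length n, pad r.
reflect_idx <- function(n, r) {
  if (r >= n) stop("padding exceeds frame size")
  c(r:1, 1:n, n:(n - r + 1))
}

# Centered moving-window sums of a padded matrix, window w (odd).
# `xp` must already be reflect-padded by (w-1)/2 on each side.
box_sum_padded <- function(xp, w) {
  cs <- rbind(0, apply(xp, 2, cumsum))
  v <- cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- cbind(0, t(apply(v, 1, cumsum)))
  cs2[, (w + 1):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

# Centered moving-window mean with reflective borders (same shape as x).
box_mean <- function(x, w) {
  r <- (w - 1L) %/% 2L
  xp <- x[reflect_idx(nrow(x), r), reflect_idx(ncol(x), r), drop = FALSE]
  box_sum_padded(xp, w) / (w * w)
}

check_roi <- function(roi, nr, nc) {
  if (length(roi) != 4L || any(!is.finite(roi)))
    stop_especkle("roi must be c(r0, r1, c0, c1), 0-based half-open",
                  "especkle_invalid_roi")
  roi <- as.integer(roi)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nr || roi[4] > nc ||
      roi[1] >= roi[2] || roi[3] >= roi[4])
    stop_especkle("roi out of frame bounds or empty", "especkle_invalid_roi")
  roi
}

# Evaluate a function with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Full-precision numeric formatting for CSV round-trips.
num17 <- function(x) formatC(x, digits = 17, format = "g")
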