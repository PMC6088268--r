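#' Hemoglobin extinction coefficient table
#'
#' Absorptivities of oxy- and deoxy-hemoglobin at the two illumination
#' wavelengths, in per (mM x mm), from the standard compiled hemoglobin
#' absorptivity tabulation. The pair straddles the near-infrared isosbestic
#' point: at 660 nm deoxy-hemoglobin absorbs far more strongly than
#' oxy-hemoglobin, at 830 nm the order reverses — the property that makes
#' ratiometric oxygenation imaging possible. The effective optical
#' pathlength and differential pathlength factor are lumped into
#' `pathlength_factor` (default 1), so all derived concentration changes
#' are in relative units.
#'
#' @param wavelengths Wavelengths in nm (default `c(660, 830)`).
#' @param eps_hbo2,eps_hb Extinction coefficients per wavelength, per
#'   (mM x mm).
#' @param pathlength_factor Lumped pathlength scale (dimensionless).
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths = c(660, 830),
                             eps_hbo2 = c(0.0320, 0.0974),
                             eps_hb = c(0.3227, 0.0693),
                             pathlength_factor = 1) {
  if (length(eps_hbo2) != length(wavelengths) ||
      length(eps_hb) != length(wavelengths))
    stop_especkle("one eps value per wavelength required",
                  "especkle_invalid_extinction")
  if (any(eps_hbo2 <= 0) || any(eps_hb <= 0))
    stop_especkle("extinction coefficients must be positive",
                  "especkle_invalid_extinction")
  i660 <- match(660, wavelengths); i830 <- match(830, wavelengths)
  if (!is.na(i660) && eps_hb[i660] <= eps_hbo2[i660])
    stop_especkle("at 660 nm deoxy-Hb must absorb more than HbO2",
                  "especkle_invalid_extinction")
  if (!is.na(i830) && eps_hbo2[i830] <= eps_hb[i830])
    stop_especkle("at 830 nm HbO2 must absorb more than deoxy-Hb",
                  "especkle_invalid_extinction")
  if (pathlength_factor <= 0)
    stop_especkle("pathlength_factor must be positive",
                  "especkle_invalid_extinction")
  structure(list(wavelengths = wavelengths,
                 eps_hbo2 = eps_hbo2, eps_hb = eps_hb,
                 pathlength_factor = pathlength_factor),
            class = "extinction_table")
}

extinction_row <- function(table, wavelength) {
  i <- match(wavelength, table$wavelengths)
  if (is.na(i))
    stop_especkle(sprintf("no extinction entry for %g nm", wavelength),
                  "especkle_invalid_extinction")
  c(hbo2 = table$eps_hbo2[i], hb = table$eps_hb[i])
}

#' Pair frames across the two wavelength streams
#'
#' Greedy nearest-timestamp pairing of the 660 and 830 nm stacks (the lasers
#' alternate, synchronized with the camera, so matched pairs are offset by
#' about half a frame period). Pairs further apart than `max_lag` are
#' dropped and counted; each frame is used at most once.
#'
#' @param stack660,stack830 [speckle_stack()] objects.
#' @param max_lag Maximum admissible |timestamp difference| in seconds;
#'   default one nominal frame period (or the median 660 nm frame interval).
#' @return A data frame with columns `index660`, `index830`, `lag`
#'   (seconds, `t830 - t660`), ordered by time, with attribute `dropped`
#'   (count of inadmissible candidate pairs).
#' @export
pair_frames <- function(stack660, stack830, max_lag = NULL) {
  stopifnot(inherits(stack660, "speckle_stack"),
            inherits(stack830, "speckle_stack"))
  t1 <- stack660$timestamps; t2 <- stack830$timestamps
  if (length(t1) == 0L || length(t2) == 0L)
    stop_especkle("both stacks must be nonempty", "especkle_unalignable")
  max_lag <- max_lag %||%
    (1 / (stack660$metadata$nominal_frame_rate %||%
            (1 / median(diff(t1)))))
  # candidates: for each 660 frame its two bracketing 830 frames
  pos <- findInterval(t1, t2)
  cand <- rbind(
    data.frame(i = seq_along(t1), j = pos),
    data.frame(i = seq_along(t1), j = pos + 1L))
  cand <- cand[cand$j >= 1L & cand$j <= length(t2), ]
  cand$lag <- t2[cand$j] - t1[cand$i]
  admissible <- abs(cand$lag) <= max_lag
  dropped <- sum(!admissible)
  cand <- cand[admissible, ]
  # ties at exactly half a frame period (perfect interleaving) are broken
  # toward the 830 frame *following* its 660 partner, matching the laser
  # switching order
  cand <- cand[order(abs(cand$lag), -cand$lag), ]
  used1 <- logical(length(t1)); used2 <- logical(length(t2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used1[i] && !used2[j]) {
      keep[r] <- TRUE; used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  res <- cand[keep, ]
  if (nrow(res) == 0L)
    stop_especkle("wavelength streams unalignable: no pairs within max_lag",
                  "especkle_unalignable")
  res <- res[order(t1[res$i]), ]
  out <- data.frame(index660 = res$i, index830 = res$j, lag = res$lag)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Ratiometric oxygenation map from a 660/830 nm frame pair
#'
#' Per-pixel ratio of locally mean-smoothed intensities `I660 / I830`.
#' Because deoxy-hemoglobin dominates absorption at 660 nm while
#' oxy-hemoglobin dominates at 830 nm, a rise in oxygenation raises the
#' 660 nm reflectance relative to 830 nm and hence the ratio; the map is
#' reported as the raw ratio and any color rendering is a presentation
#' choice.
#'
#' @param frame660,frame830 Equal-shape 2-D intensity matrices.
#' @param smoothing_window Odd local-mean window in pixels (default 7).
#' @return A matrix of ratios; pixels whose smoothed 830 nm mean is 0 are
#'   `NaN`.
#' @export
oxygenation_map <- function(frame660, frame830, smoothing_window = 7L) {
  if (!is.matrix(frame660) || !is.matrix(frame830) ||
      !all(dim(frame660) == dim(frame830)))
    stop_especkle("frames must be matrices of identical shape",
                  "especkle_shape_mismatch")
  w <- as.integer(smoothing_window)
  if (w %% 2L == 0L || w < 1L)
    stop_especkle("smoothing_window must be odd", "especkle_invalid_window")
  m660 <- if (w == 1L) frame660 else box_mean(frame660, w)
  m830 <- if (w == 1L) frame830 else box_mean(frame830, w)
  r <- m660 / m830
  r[m830 == 0] <- NaN
  r
}

#' Chromophore concentration changes via the modified Beer-Lambert law
#'
#' For ROI-mean intensity series at the two wavelengths, computes the change
#' in optical density against a reference sample,
#' `dOD(lambda, t) = -ln(I(lambda, t) / I(lambda, ref))`, and solves the
#' 2x2 linear system `dOD = pathlength_factor * E %*% c(dC_HbO2, dC_Hb)`
#' per sample, where `E` is the extinction matrix. With
#' `pathlength_factor = 1` the returned concentration changes are in
#' relative mM units.
#'
#' @param series660,series830 Positive ROI-mean intensities over time, equal
#'   length `>= 2`.
#' @param t Optional sample times (seconds).
#' @param reference_index Index of the reference sample (default 1; choose a
#'   pre-occlusion sample to baseline against normal flow).
#' @param table An [extinction_table()] containing 660 and 830 nm.
#' @return A data frame with columns `t`, `d_hbo2`, `d_hb`, `d_total`
#'   (`d_total = d_hbo2 + d_hb` exactly; all zero at the reference sample).
#'   Samples with nonpositive intensity are `NaN` (counted in a warning).
#' @export
chromophore_deltas <- function(series660, series830, t = NULL,
                               reference_index = 1L,
                               table = extinction_table()) {
  n <- length(series660)
  if (length(series830) != n || n < 2L)
    stop_especkle("series must have equal length >= 2",
                  "especkle_invalid_series")
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > n)
    stop_especkle("reference_index out of range", "especkle_invalid_series")
  e660 <- extinction_row(table, 660)
  e830 <- extinction_row(table, 830)
  E <- rbind(e660, e830) * table$pathlength_factor
  if (abs(det(E)) < 1e-12)
    stop_especkle("extinction matrix is singular", "especkle_invalid_extinction")
  bad <- series660 <= 0 | series830 <= 0
  if (bad[reference_index])
    stop_especkle("reference sample has nonpositive intensity",
                  "especkle_invalid_series")
  if (any(bad))
    warning(sum(bad), " sample(s) with nonpositive intensity set to NaN")
  od <- rbind(-log(series660 / series660[reference_index]),
              -log(series830 / series830[reference_index]))
  dc <- solve(E, od)
  dc[, bad] <- NaN
  t <- t %||% seq_len(n)
  data.frame(t = t, d_hbo2 = dc[1, ], d_hb = dc[2, ],
             d_total = dc[1, ] + dc[2, ])
}

#' ROI-mean intensity series of a stack
#'
#' Mean raw intensity over a region of interest per frame — the intensity
#' channel feeding the modified Beer-Lambert computation (absorption acts on
#' intensity, not on contrast).
#'
#' @param stack A [speckle_stack()].
#' @param roi 0-based half-open bounds `c(r0, r1, c0, c1)`; `NULL` for the
#'   full frame.
#' @return A data frame with columns `t`, `intensity`.
#' @export
roi_intensity_series <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "speckle_stack"))
  d <- dim(stack$frames)
  roi <- check_roi(roi %||% c(0, d[2], 0, d[3]), d[2], d[3])
  rows <- (roi[1] + 1):roi[2]; cols <- (roi[3] + 1):roi[4]
  i <- vapply(seq_len(d[1]),
              function(f) mean(stack$frames[f, rows, cols]), numeric(1))
  data.frame(t = stack$timestamps, intensity = i)
}
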