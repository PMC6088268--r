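#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every tunable of the processing chain: inputs, ROI, contrast
#' window, fiber filter policy, physiological bands, extinction table and
#' output location. Round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param image_paths TIFF path(s), one per wavelength or one interleaved.
#' @param timestamp_path Timestamp CSV path.
#' @param output_dir Directory for artifacts (created if needed).
#' @param roi 0-based half-open `c(r0, r1, c0, c1)` or `NULL` (full frame).
#' @param window_size Odd contrast window (default 7).
#' @param fiber_filter `"auto"` (detect the bundle carrier and cut at half
#'   its frequency), `"none"`, or a [fiber_filter_spec()].
#' @param cardiac_band,respiratory_band Hz pairs (defaults 1-4, 0.1-1).
#' @param extinction An [extinction_table()].
#' @param reference_index Beer-Lambert reference sample (default 1).
#' @param max_lag Frame-pairing tolerance in seconds (`NULL`: one frame
#'   period).
#' @param min_shift_sd,min_duration Occlusion-detector thresholds.
#' @param oximetry_on_contrast If `TRUE`, ratio contrast maps instead of raw
#'   intensities for the oxygenation map (default `FALSE`: absorption acts
#'   on intensity).
#' @param figures Write PNG figures (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(image_paths, timestamp_path, output_dir,
                            roi = NULL, window_size = 7L,
                            fiber_filter = "auto",
                            cardiac_band = c(1, 4),
                            respiratory_band = c(0.1, 1),
                            extinction = extinction_table(),
                            reference_index = 1L,
                            max_lag = NULL,
                            min_shift_sd = 3, min_duration = 5,
                            oximetry_on_contrast = FALSE,
                            figures = TRUE) {
  structure(list(image_paths = image_paths, timestamp_path = timestamp_path,
                 output_dir = output_dir, roi = roi,
                 window_size = as.integer(window_size),
                 fiber_filter = fiber_filter,
                 cardiac_band = cardiac_band,
                 respiratory_band = respiratory_band,
                 extinction = extinction,
                 reference_index = as.integer(reference_index),
                 max_lag = max_lag,
                 min_shift_sd = min_shift_sd, min_duration = min_duration,
                 oximetry_on_contrast = isTRUE(oximetry_on_contrast),
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$fiber_filter <- if (inherits(x$fiber_filter, "fiber_filter_spec"))
    unclass(x$fiber_filter) else x$fiber_filter
  x$extinction <- unclass(x$extinction)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ff <- x$fiber_filter
  if (is.list(ff)) ff <- fiber_filter_spec(ff$cutoff, ff$order)
  pipeline_config(
    image_paths = x$image_paths, timestamp_path = x$timestamp_path,
    output_dir = x$output_dir, roi = x$roi,
    window_size = x$window_size, fiber_filter = ff,
    cardiac_band = x$cardiac_band, respiratory_band = x$respiratory_band,
    extinction = extinction_table(x$extinction$wavelengths,
                                  x$extinction$eps_hbo2,
                                  x$extinction$eps_hb,
                                  x$extinction$pathlength_factor),
    reference_index = x$reference_index, max_lag = x$max_lag,
    min_shift_sd = x$min_shift_sd, min_duration = x$min_duration,
    oximetry_on_contrast = x$oximetry_on_contrast, figures = x$figures)
}

#' Run the full eLASCA analysis pipeline
#'
#' Executes fiber filtering, contrast mapping, contrast time series,
#' spectral rate extraction, oximetry and occlusion detection on recorded
#' (or simulated) stacks, writing every artifact plus a JSON report and a
#' manifest with content hashes. The analysis path draws no random numbers,
#' so two runs on the same inputs produce byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest_write(out, artifacts, complete = FALSE, failed_stage = name)
      stop_especkle(sprintf("pipeline stage '%s' failed: %s",
                            name, conditionMessage(e)),
                    "especkle_stage_failure")
    })
  }

  stacks <- stage("read", read_stack(config$image_paths, config$timestamp_path))
  message("pipeline: read ", length(stacks), " wavelength stream(s)")

  # --- fiber filter -------------------------------------------------------
  stacks <- stage("fiber_filter", {
    lapply(stacks, function(st) {
      spec <- config$fiber_filter
      if (identical(spec, "none")) return(st)
      if (identical(spec, "auto")) spec <- auto_filter_spec(st)
      if (is.null(spec)) {
        message("pipeline: no fiber pattern detected at ", st$wavelength,
                " nm; filtering skipped")
        return(st)
      }
      message(sprintf("pipeline: filtering %s nm (cutoff %.4f c/px, order %d)",
                      st$wavelength, spec$cutoff, spec$order))
      filter_stack(st, spec)
    })
  })

  # --- contrast maps and series ------------------------------------------
  series <- list()
  stage("contrast", {
    for (key in names(stacks)) {
      st <- stacks[[key]]
      km <- contrast_map(get_frame(st, 1L), config$window_size)
      p <- file.path(out, sprintf("contrast_map_%snm.tif", key))
      write_map(km, p); artifacts <- c(artifacts, p)
      s <- roi_contrast_series(st, config$roi, config$window_size)
      series[[key]] <- s
      p <- file.path(out, sprintf("contrast_series_%snm.csv", key))
      write_contrast_series(s, p); artifacts <- c(artifacts, p)
    }
  })

  # --- spectral rates (first/660 nm stream) ------------------------------
  rate_key <- if ("660" %in% names(series)) "660" else names(series)[1]
  spec_obj <- NULL
  report$rates <- stage("rates", {
    s <- resample_double(detrend_series(series[[rate_key]]))
    spec_obj <- power_spectrum(s)
    p <- file.path(out, "spectrum.csv")
    write.csv(data.frame(freq_hz = num17(spec_obj$freq),
                         power = num17(spec_obj$power)),
              p, row.names = FALSE, quote = FALSE)
    artifacts <- c(artifacts, p)
    est <- tryCatch(
      attribute_peaks(spec_obj, config$cardiac_band, config$respiratory_band),
      especkle_band_beyond_nyquist = function(e) e)
    if (inherits(est, "condition")) {
      message("pipeline: ", conditionMessage(est))
      list(aliased_or_out_of_band = TRUE, detail = conditionMessage(est))
    } else {
      message(sprintf("pipeline: cardiac %.4g /min, respiratory %.4g /min",
                      primary_rate(est, "cardiac"),
                      primary_rate(est, "respiratory")))
      list(aliased_or_out_of_band = FALSE, estimates = est)
    }
  })

  # --- occlusion ---------------------------------------------------------
  report$occlusion <- stage("occlusion", {
    resp <- if (!isTRUE(report$rates$aliased_or_out_of_band))
      primary_rate(report$rates$estimates, "respiratory") else NA_real_
    sp <- if (is.finite(resp) && resp > 0) 60 / resp else NULL
    call <- tryCatch(
      detect_occlusion(series[[rate_key]], config$min_shift_sd,
                       config$min_duration, spike_period = sp),
      especkle_too_few_samples = function(e) NULL)
    if (is.null(call)) NULL else unclass(call)
  })

  # --- oximetry ----------------------------------------------------------
  report$oximetry <- stage("oximetry", {
    if (!all(c("660", "830") %in% names(stacks))) {
      message("pipeline: oximetry skipped (needs both 660 and 830 nm)")
      NULL
    } else {
      s660 <- stacks[["660"]]; s830 <- stacks[["830"]]
      pairs <- pair_frames(s660, s830, config$max_lag)
      f660 <- get_frame(s660, pairs$index660[1])
      f830 <- get_frame(s830, pairs$index830[1])
      if (config$oximetry_on_contrast) {
        f660 <- contrast_map(f660, config$window_size)
        f830 <- contrast_map(f830, config$window_size)
      }
      omap <- oxygenation_map(f660, f830, config$window_size)
      p <- file.path(out, "oxygenation_ratio_map.tif")
      write_map(omap, p); artifacts <- c(artifacts, p)
      i660 <- roi_intensity_series(s660, config$roi)
      i830 <- roi_intensity_series(s830, config$roi)
      dc <- chromophore_deltas(i660$intensity[pairs$index660],
                               i830$intensity[pairs$index830],
                               t = (i660$t[pairs$index660] +
                                      i830$t[pairs$index830]) / 2,
                               reference_index = config$reference_index,
                               table = config$extinction)
      p <- file.path(out, "chromophore_deltas.csv")
      write.csv(data.frame(t_seconds = num17(dc$t),
                           d_hbo2 = num17(dc$d_hbo2),
                           d_hb = num17(dc$d_hb),
                           d_total = num17(dc$d_total)),
                p, row.names = FALSE, quote = FALSE)
      artifacts <- c(artifacts, p)
      list(n_pairs = nrow(pairs), dropped_pairs = attr(pairs, "dropped"),
           mean_abs_lag = mean(abs(pairs$lag)),
           ratio_map_mean = mean(omap[is.finite(omap)]),
           final_d_hbo2 = dc$d_hbo2[nrow(dc)],
           final_d_total = dc$d_total[nrow(dc)],
           deltas_path = "chromophore_deltas.csv")
    }
  })

  # --- figures -----------------------------------------------------------
  if (config$figures) stage("figures", {
    p <- file.path(out, "fig_contrast_map.png")
    png(p, 600, 500); plot_contrast_map(
      contrast_map(get_frame(stacks[[rate_key]], 1L), config$window_size))
    dev.off(); artifacts <- c(artifacts, p)
    p <- file.path(out, "fig_contrast_series.png")
    png(p, 700, 400); plot(series[[rate_key]]); dev.off()
    artifacts <- c(artifacts, p)
    if (!is.null(spec_obj)) {
      p <- file.path(out, "fig_spectrum.png")
      png(p, 700, 400); plot(spec_obj); dev.off()
      artifacts <- c(artifacts, p)
    }
    if (!is.null(report$oximetry)) {
      dc <- read.csv(file.path(out, "chromophore_deltas.csv"))
      p <- file.path(out, "fig_delta_hbo2.png")
      png(p, 700, 400)
      plot(dc$t_seconds, dc$d_hbo2, type = "l", col = "firebrick",
           xlab = "time (s)", ylab = expression(Delta * "C HbO2 (rel. mM)"),
           main = "Oxy-hemoglobin concentration change")
      abline(h = 0, lty = 3)
      dev.off(); artifacts <- c(artifacts, p)
    }
  })

  report$inputs <- list(image_paths = unname(config$image_paths),
                        timestamp_path = config$timestamp_path,
                        roi = config$roi, window_size = config$window_size)
  rp <- file.path(out, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  artifacts <- c(artifacts, rp)
  manifest_write(out, artifacts, complete = TRUE)
  invisible(report)
}

manifest_write <- function(out, artifacts, complete, failed_stage = NULL) {
  files <- artifacts[file.exists(artifacts)]
  jsonlite::write_json(
    list(complete = complete, failed_stage = failed_stage,
         artifacts = data.frame(
           file = basename(files),
           md5 = unname(tools::md5sum(files)))),
    file.path(out, "manifest.json"), auto_unbox = TRUE, null = "null",
    pretty = TRUE)
}
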