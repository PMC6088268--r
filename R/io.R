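#' Write speckle stacks, timestamps and ground truth to disk
#'
#' One multi-page 16-bit TIFF per wavelength (holding the 12-bit data), a
#' combined timestamp CSV (`frame_index`, `wavelength_nm`, `t_seconds`), a
#' metadata sidecar JSON, and — for simulator output — the ground truth as
#' JSON.
#'
#' @param x An `especkle_simulation` (from [simulate_stack()]), a named list
#'   of [speckle_stack()]s, or a single stack.
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"stack"`).
#' @return Invisibly, a named list of written paths.
#' @export
write_stack <- function(x, dir, basename = "stack") {
  gt <- NULL
  if (inherits(x, "especkle_simulation")) { gt <- x$ground_truth; x <- x$stacks }
  if (inherits(x, "speckle_stack")) x <- setNames(list(x), as.character(x$wavelength))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(images = character(0))
  ts_rows <- list()
  meta <- list()
  for (key in names(x)) {
    st <- x[[key]]
    nf <- n_frames(st)
    path <- file.path(dir, sprintf("%s_%snm.tif", basename, key))
    pages <- lapply(seq_len(nf), function(i) st$frames[i, , , drop = TRUE] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    paths$images[key] <- path
    ts_rows[[key]] <- data.frame(frame_index = seq_len(nf) - 1L,
                                 wavelength_nm = st$wavelength,
                                 t_seconds = num17(st$timestamps))
    meta[[key]] <- list(file = base::basename(path),
                        wavelength_nm = st$wavelength,
                        exposure_time_s = st$exposure_time,
                        bit_depth = st$bit_depth,
                        metadata = st$metadata)
  }
  ts <- do.call(rbind, ts_rows)
  ts <- ts[order(as.numeric(ts$t_seconds)), ]
  paths$timestamps <- file.path(dir, sprintf("%s_timestamps.csv", basename))
  write.csv(ts, paths$timestamps, row.names = FALSE, quote = FALSE)
  paths$metadata <- file.path(dir, sprintf("%s_meta.json", basename))
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(gt)) {
    paths$ground_truth <- file.path(dir, sprintf("%s_ground_truth.json", basename))
    jsonlite::write_json(
      list(seed = gt$seed,
           physiology = unclass(gt$params),
           acquisition = unclass(gt$config),
           per_frame_tau_c = gt$per_frame_tau_c,
           per_frame_chromophores = lapply(gt$per_frame_chromophores,
                                           function(m) as.data.frame(m)),
           timestamps = gt$timestamps),
      paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

#' Read speckle stacks from TIFF + timestamp CSV
#'
#' Reads one or more multi-page TIFFs and a timestamp table, demultiplexes
#' wavelength streams using the table's `wavelength_nm` column, validates
#' per-stream monotone timestamps and frame counts, and attaches exposure /
#' bit depth from the metadata sidecar when present.
#'
#' @param image_paths Character vector of TIFF paths: either one file per
#'   wavelength (as written by [write_stack()]) or a single interleaved
#'   file whose page order matches the timestamp rows.
#' @param timestamp_path CSV with columns `frame_index`, `wavelength_nm`,
#'   `t_seconds`.
#' @param metadata_path Optional sidecar JSON (auto-discovered next to the
#'   timestamp file when named `*_meta.json`).
#' @return A named list of [speckle_stack()], one per wavelength.
#' @export
read_stack <- function(image_paths, timestamp_path, metadata_path = NULL) {
  ts <- read.csv(timestamp_path)
  need <- c("frame_index", "wavelength_nm", "t_seconds")
  if (!all(need %in% names(ts)))
    stop_especkle("timestamp CSV must have columns frame_index, wavelength_nm, t_seconds",
                  "especkle_invalid_io")
  if (is.null(metadata_path)) {
    guess <- sub("_timestamps\\.csv$", "_meta.json", timestamp_path)
    if (file.exists(guess) && guess != timestamp_path) metadata_path <- guess
  }
  meta <- if (!is.null(metadata_path)) jsonlite::read_json(metadata_path) else list()
  wls <- sort(unique(ts$wavelength_nm))

  load_pages <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) {
      m <- round(p * 65535)
      storage.mode(m) <- "integer"
      m
    })
  }

  # match files to wavelengths via names or filename ("..._660nm.tif")
  wl_of <- function(path) {
    nm <- names(image_paths)[match(path, image_paths)]
    if (!is.null(nm) && nzchar(nm %||% "")) return(as.numeric(nm))
    hit <- regmatches(path, regexpr("([0-9]+)nm", path))
    if (length(hit)) return(as.numeric(sub("nm", "", hit)))
    NA_real_
  }

  stacks <- list()
  single_wl <- if (length(image_paths) == 1L) wl_of(image_paths) else NA_real_
  if (length(image_paths) == 1L && !is.na(single_wl)) {
    # one per-wavelength file; the CSV may still list all streams
    sub <- ts[ts$wavelength_nm == single_wl, ]
    if (nrow(sub) == 0L)
      stop_especkle(sprintf("unknown wavelength label %g nm", single_wl),
                    "especkle_invalid_io")
    pages <- load_pages(image_paths)
    if (length(pages) != nrow(sub))
      stop_especkle(sprintf("page count (%d) != timestamp rows (%d) for %g nm",
                            length(pages), nrow(sub), single_wl),
                    "especkle_invalid_io")
    sub <- sub[order(sub$frame_index), ]
    stacks[[as.character(single_wl)]] <-
      build_stack(pages, sub$t_seconds, single_wl, meta)
  } else if (length(image_paths) == 1L && length(wls) > 1L) {
    pages <- load_pages(image_paths)
    if (length(pages) != nrow(ts))
      stop_especkle(sprintf("page count (%d) != timestamp rows (%d)",
                            length(pages), nrow(ts)), "especkle_invalid_io")
    for (wl in wls) {
      idx <- which(ts$wavelength_nm == wl)   # pages map to CSV rows in order
      stacks[[as.character(wl)]] <-
        build_stack(pages[idx], ts$t_seconds[idx], wl, meta)
    }
  } else {
    if (length(image_paths) != length(wls))
      stop_especkle("one image file per wavelength expected",
                    "especkle_invalid_io")
    for (path in image_paths) {
      wl <- wl_of(path)
      if (is.na(wl))
        stop_especkle("cannot infer wavelength for image file; name the paths",
                      "especkle_invalid_io")
      if (!wl %in% wls)
        stop_especkle(sprintf("unknown wavelength label %g nm", wl),
                      "especkle_invalid_io")
      sub <- ts[ts$wavelength_nm == wl, ]
      pages <- load_pages(path)
      if (length(pages) != nrow(sub))
        stop_especkle(sprintf("page count (%d) != timestamp rows (%d) for %g nm",
                              length(pages), nrow(sub), wl),
                      "especkle_invalid_io")
      sub <- sub[order(sub$frame_index), ]
      stacks[[as.character(wl)]] <-
        build_stack(pages, sub$t_seconds, wl, meta)
    }
  }
  stacks[order(as.numeric(names(stacks)))]
}

build_stack <- function(pages, t, wl, meta) {
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_especkle(sprintf("timestamps for %g nm are not strictly increasing", wl),
                  "especkle_invalid_io")
  d <- dim(pages[[1]])
  frames <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  m <- meta[[as.character(wl)]]
  speckle_stack(frames, t, wl,
                exposure_time = m$exposure_time_s %||% NA_real_,
                bit_depth = m$bit_depth %||% 12L,
                metadata = c(m$metadata %||% list(), list(read_from_disk = TRUE)))
}

#' Write / read a contrast series as CSV
#'
#' Columns `t_seconds`, `contrast`; values are written at full precision so
#' a round trip is lossless.
#'
#' @param series A [contrast_series()].
#' @param path CSV path.
#' @return `write_contrast_series` returns the path invisibly;
#'   `read_contrast_series` a [contrast_series()].
#' @export
write_contrast_series <- function(series, path) {
  stopifnot(inherits(series, "contrast_series"))
  df <- data.frame(t_seconds = num17(series$t), contrast = num17(series$k))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contrast_series
#' @export
read_contrast_series <- function(path) {
  df <- read.csv(path)
  contrast_series(df$t_seconds, df$contrast)
}

#' Write / read a 2-D map (contrast or oxygenation ratio) as TIFF
#'
#' Maps are stored as 32-bit TIFF normalized by their maximum, with a JSON
#' sidecar (`<path>.json`) recording the scale and the NaN mask, so the
#' round trip is lossless to about 1e-9 relative precision. NaN pixels
#' (dark windows) are stored as 0 and restored on read.
#'
#' @param map Numeric matrix.
#' @param path Output TIFF path.
#' @return `write_map` returns the path invisibly; `read_map` the matrix.
#' @export
write_map <- function(map, path) {
  m <- map
  nan_idx <- which(!is.finite(m))
  m[nan_idx] <- 0
  scale <- max(m, 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(scale = scale, dim = dim(m),
                            nan_indices = nan_idx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * side$scale
  if (length(side$nan_indices)) m[side$nan_indices] <- NaN
  m
}
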