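# TIFF/YAML/JSON input-output: frame stacks, calibration maps, manifests.
#
# Frame stacks are 16-bit multi-page TIFFs. Calibration and derived maps
# are single-page 32-bit float TIFFs with canonical names plus a JSON
# sidecar recording units and provenance. The installed TIFF reader handles
# arbitrary float32 data, but no installed writer does (values outside
# [0, 1] are undefined), so float maps are written by a minimal
# uncompressed little-endian writer below and round-tripped through
# `tiff::readTIFF` in the tests.

#' Read a (multi-page) TIFF stack
#'
#' @param path TIFF file.
#' @param pages optional integer page indices for page-wise (streaming)
#'   access; default reads all pages.
#' @return numeric array `rows x cols (x pages)`; integer-valued for
#'   integer TIFFs.
#' @export
read_stack <- function(path, pages = NULL) {
  imgs <- tiff::readTIFF(path, all = pages %||% TRUE, as.is = TRUE)
  if (is.matrix(imgs)) return(imgs)
  if (!is.list(imgs)) imgs <- list(imgs)
  dims <- unique(lapply(imgs, dim))
  if (length(dims) != 1L) stop_arg("mixed page shapes in '%s'", path)
  if (length(imgs) == 1L && length(pages) == 1L) return(imgs[[1]])
  arr <- array(0, c(dims[[1]], length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]
  arr
}

count_tiff_pages <- function(path) {
  a <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  # metadata-only read: either one list with per-page vector fields, or a
  # list of per-page attribute lists
  if (is.list(a) && length(a) && is.list(a[[1]])) length(a)
  else length(a[["width"]] %||% a[[1]])
}

#' Write an integer frame stack as a 16-bit multi-page TIFF
#'
#' @param frames `rows x cols (x n)` array of ADU counts in
#'   `[0, 65535]`.
#' @param path output file.
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (min(frames) < 0 || max(frames) > 65535) {
    stop_arg("frame values must lie in [0, 65535] for 16-bit storage")
  }
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(i) frames[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# --- minimal float32 TIFF writer (single or multi page, uncompressed) -----

write_float_tiff <- function(x, path) {
  pages <- if (is.matrix(x)) list(x) else {
    lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  writeChar("II", con, eos = NULL); w16(42L); w32(8L)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); wdt <- ncol(m)
    nbytes <- 4L * h * wdt
    data_off <- offset + ifd_size
    next_ifd <- if (p < length(pages)) data_off + nbytes else 0L
    w16(n_entries)
    entry(256L, 3L, 1L, wdt)          # ImageWidth
    entry(257L, 3L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, 32L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)     # StripOffsets
    entry(278L, 3L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)       # StripByteCounts
    entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    w32(next_ifd)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    offset <- next_ifd
  }
  invisible(path)
}

# --- calibration / derived map directories --------------------------------

map_files <- list(
  camera_calibration = c(baseline = "baseline.tif",
                         dark_current_adu = "dark_current_per_s.tif",
                         read_noise_sq_adu = "read_noise_sq.tif",
                         thermal_noise_sq_adu = "thermal_noise_sq_per_s.tif",
                         gain = "gain.tif",
                         flatfield = "flatfield.tif"))

derived_file_names <- function(t) {
  t_ms <- signif(1000 * t, 8)
  c(offset = sprintf("offset_%gms.tif", t_ms),
    variance = sprintf("variance_%gms.tif", t_ms),
    photon_response = "photon_response.tif")
}

#' Write calibration or derived maps as float TIFFs with a JSON sidecar
#'
#' Calibration maps use the canonical names `baseline.tif`,
#' `dark_current_per_s.tif`, `read_noise_sq.tif`,
#' `thermal_noise_sq_per_s.tif`, `gain.tif`, `flatfield.tif`; derived maps
#' `offset_<t>ms.tif`, `variance_<t>ms.tif`, `photon_response.tif` — the
#' trio consumed by map-based sCMOS correction algorithms. The sidecar
#' (`maps.json`) records units, exposure times, frame counts and software
#' version.
#'
#' @param x a `camera_calibration` or `derived_maps` object.
#' @param dir output directory.
#' @param overwrite refuse to write into an existing directory unless TRUE.
#' @export
write_maps <- function(x, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop_arg("'%s' exists; use overwrite = TRUE", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(
    schema_version = 1L,
    software = paste0("darkcal ", as.character(utils::packageVersion("darkcal"))),
    units = list(offset = "ADU", variance = "ADU^2", baseline = "ADU",
                 dark_current = "ADU/s", read_noise_sq = "ADU^2",
                 thermal_noise_sq = "ADU^2/s", gain = "ADU/electron",
                 photon_response = "ADU/electron", exposure_time = "ms"))
  if (inherits(x, "camera_calibration")) {
    files <- map_files$camera_calibration
    for (nm in names(files)) {
      m <- x[[nm]]
      m[!is.finite(m)] <- NaN # NA has no float32 representation
      write_float_tiff(m, file.path(dir, files[[nm]]))
    }
    sidecar$kind <- "calibration"
    sidecar$median_gain <- x$median_gain
    sidecar$exposure_times_ms <- 1000 * x$exposure_times
    sidecar$n_frames <- x$n_frames
  } else if (inherits(x, "derived_maps")) {
    files <- derived_file_names(x$exposure_time)
    for (nm in names(files)) {
      write_float_tiff(x[[nm]], file.path(dir, files[[nm]]))
    }
    sidecar$kind <- "derived"
    sidecar$exposure_time_ms <- 1000 * x$exposure_time
  } else {
    stop_arg("'x' must be a camera_calibration or derived_maps object")
  }
  sidecar$files <- as.list(files)
  jsonlite::write_json(sidecar, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read maps written by [write_maps]
#'
#' @param dir directory containing `maps.json`.
#' @return list of map matrices plus the sidecar metadata under `$meta`.
#' @export
read_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  maps <- lapply(meta$files, function(f) tiff::readTIFF(file.path(dir, f)))
  out <- c(maps, list(meta = meta))
  if (identical(meta$kind, "derived")) {
    out <- structure(list(exposure_time = meta$exposure_time_ms / 1000,
                          offset = maps$offset, variance = maps$variance,
                          photon_response = maps$photon_response,
                          meta = meta),
                     class = "derived_maps")
  }
  out
}

# --- camera ground truth and exposure-series manifests --------------------

gt_channels <- c("baseline", "dark_current", "read_noise", "gain", "flatfield")

#' Persist a synthetic camera ground truth
#'
#' Maps go into one multi-channel float TIFF (channel order: baseline, dark
#' current, read noise, gain, flatfield), metadata into a YAML sidecar.
#' @param gt a `camera_ground_truth`.
#' @param path base path; writes `<path>.tif` and `<path>.yaml`.
#' @export
write_camera <- function(gt, path) {
  arr <- array(0, c(gt$shape, length(gt_channels)))
  for (i in seq_along(gt_channels)) arr[, , i] <- gt[[gt_channels[i]]]
  write_float_tiff(arr, paste0(path, ".tif"))
  yaml::write_yaml(list(
    kind = "camera_ground_truth", channels = gt_channels,
    shape = as.integer(gt$shape), bit_depth = gt$bit_depth,
    hot_pixels = if (nrow(gt$hot_pixels)) {
      list(row = as.integer(gt$hot_pixels[, "row"]),
           col = as.integer(gt$hot_pixels[, "col"]))
    } else list(row = integer(0), col = integer(0)),
    units = list(baseline = "ADU", dark_current = "electrons/s",
                 read_noise = "electrons", gain = "ADU/electron",
                 flatfield = "relative")
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a camera ground truth written by [write_camera]
#' @param path base path used at write time.
#' @export
read_camera <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  gt <- stats::setNames(pages, meta$channels)
  hp <- cbind(row = as.integer(meta$hot_pixels$row),
              col = as.integer(meta$hot_pixels$col))
  structure(c(list(shape = as.integer(meta$shape)), gt,
              list(bit_depth = as.integer(meta$bit_depth), hot_pixels = hp)),
            class = "camera_ground_truth")
}

#' Export an exposure series as TIFF stacks plus a YAML manifest
#'
#' One 16-bit multi-page TIFF per exposure time; the manifest records the
#' schedule and exposure times explicitly in milliseconds.
#' @param series an `exposure_series`.
#' @param dir output directory.
#' @param seed optional seed to record for provenance.
#' @param overwrite allow writing into an existing directory.
#' @export
write_series <- function(series, dir, seed = NULL, overwrite = FALSE) {
  stopifnot(inherits(series, "exposure_series"))
  if (dir.exists(dir) && !overwrite) {
    stop_arg("'%s' exists; use overwrite = TRUE", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("dark_%04.0fms.tif", 1000 * series$exposure_times)
  for (i in seq_along(files)) {
    write_stack(series$frames[[i]], file.path(dir, files[i]))
  }
  d <- dim(series$frames[[1]])
  yaml::write_yaml(list(
    schema_version = 1L, kind = "exposure_series",
    exposure_times = 1000 * series$exposure_times, time_unit = "ms",
    frames_per_time = if (length(d) == 3L) d[3] else 1L,
    shape = as.integer(d[1:2]), bit_depth = series$bit_depth,
    schedule = series$schedule, files = files,
    seed = seed
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read an exposure series written by [write_series]
#' @param dir directory containing `manifest.yaml`.
#' @export
read_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (!identical(meta$time_unit, "ms") && !identical(meta$time_unit, "s")) {
    stop_arg("manifest time_unit must be 'ms' or 's'")
  }
  scale <- if (identical(meta$time_unit, "ms")) 1e-3 else 1
  frames <- lapply(meta$files, function(f) read_stack(file.path(dir, f)))
  exposure_series(unlist(meta$exposure_times) * scale, frames,
                  schedule = meta$schedule, bit_depth = meta$bit_depth)
}
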