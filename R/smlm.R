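# SMLM frame simulation through the camera model and the
# per-pixel-variance-aware MLE fitting interface.

#' Emitter ground truth
#'
#' @param x,y lateral position (nm) in the camera frame (pixel width from
#'   the PSF model; pixel (1,1) spans 0..pixel_size nm).
#' @param z axial position (nm).
#' @param photons expected photoelectrons per frame (> 0).
#' @param bg background photoelectrons per pixel per frame (>= 0).
#' @export
emitter_truth <- function(x, y, z = 0, photons, bg = 0) {
  if (photons <= 0) stop_arg("'photons' must be > 0")
  if (bg < 0) stop_arg("'bg' must be >= 0")
  structure(list(x = x, y = y, z = z, photons = photons, bg = bg),
            class = "emitter_truth")
}

#' Fluorophore/exposure presets per SMLM modality
#'
#' Mean photon counts per emitter and per frame parameterized from typical
#' PALM, STORM and DNA-PAINT experiments, together with the single-frame
#' exposure times used for them (50 ms, 50 ms and 500 ms). Photon numbers
#' differ between a cooled scientific-grade and an uncooled industry-grade
#' camera (3,420/9,000/35,100 vs 1,900/5,000/19,500). Background levels are
#' not sharply defined by those experiments and are free parameters here.
#'
#' @param modality `"palm"`, `"storm"` or `"paint"`.
#' @param camera_grade `"scmos"` (scientific) or `"industry"`.
#' @param bg override background (photoelectrons/pixel/frame).
#' @return list with `photons`, `exposure_time` (s), `bg`.
#' @export
modality_preset <- function(modality = c("palm", "storm", "paint"),
                            camera_grade = c("scmos", "industry"),
                            bg = NULL) {
  modality <- match.arg(modality)
  camera_grade <- match.arg(camera_grade)
  photons <- switch(camera_grade,
    scmos = c(palm = 3420, storm = 9000, paint = 35100),
    industry = c(palm = 1900, storm = 5000, paint = 19500))[[modality]]
  list(photons = photons,
       exposure_time = c(palm = 0.05, storm = 0.05, paint = 0.5)[[modality]],
       bg = bg %||% c(palm = 15, storm = 30, paint = 50)[[modality]],
       modality = modality, camera_grade = camera_grade)
}

# ROI window of half-width h around the pixel containing the emitter;
# returns row/col index ranges (camera frame) and the ROI origin in nm.
roi_window <- function(gt, psf, emitter, roi_size) {
  px <- psf$pixel_size
  ci <- floor(emitter$y / px) + 1L # row
  cj <- floor(emitter$x / px) + 1L # col
  h <- (roi_size - 1L) %/% 2L
  rows <- (ci - h):(ci + h)
  cols <- (cj - h):(cj + h)
  if (min(rows) < 1L || max(rows) > gt$shape[1] ||
      min(cols) < 1L || max(cols) > gt$shape[2]) {
    stop_arg("ROI extends outside the camera")
  }
  list(rows = rows, cols = cols,
       origin = c(x = (min(cols) - 1) * px, y = (min(rows) - 1) * px))
}

#' Simulate noisy single-emitter ROIs through the camera model
#'
#' Renders the expected photon map of the emitter over an ROI centered on
#' the pixel containing it, then applies the full camera model per pixel:
#' `ADU = clip(round(BL + g * (Poisson(ff * (N*E + bg) + DC*t) +
#' Normal(0, RN))), 0, sat)`. In `photon_mode = "fixed"` every repeat uses
#' the same photon count (the protocol for RMSE estimates); in
#' `"distribution"` the per-repeat photon count is drawn from
#' `photon_sampler(n)`.
#'
#' @param gt a `camera_ground_truth`.
#' @param psf a `psf_model`.
#' @param emitter an [emitter_truth]; positions in the camera frame (nm).
#' @param t exposure time (s), > 0.
#' @param n_repeats frames to simulate.
#' @param photon_mode `"fixed"` or `"distribution"`.
#' @param photon_sampler function(n) returning n photon counts
#'   (required for `"distribution"`).
#' @param roi_size odd ROI side length in pixels.
#' @param seed optional integer seed.
#' @return list with `rois` (`roi_size x roi_size x n_repeats` ADU array),
#'   `rows`, `cols` (camera indices), `origin` (nm), `truth` (emitter in
#'   ROI coordinates), `photons` (per-repeat counts).
#' @export
simulate_smlm_frames <- function(gt, psf, emitter, t, n_repeats = 1L,
                                 photon_mode = c("fixed", "distribution"),
                                 photon_sampler = NULL, roi_size = 13L,
                                 seed = NULL) {
  stopifnot(inherits(gt, "camera_ground_truth"), inherits(psf, "psf_model"),
            inherits(emitter, "emitter_truth"))
  if (t <= 0) stop_arg("'t' must be > 0")
  photon_mode <- match.arg(photon_mode)
  win <- roi_window(gt, psf, emitter, roi_size)
  E <- psf_pixel_integrals(psf, emitter$x - win$origin["x"],
                           emitter$y - win$origin["y"], emitter$z,
                           c(roi_size, roi_size))
  ff <- gt$flatfield[win$rows, win$cols]
  dc <- gt$dark_current[win$rows, win$cols]
  rn <- gt$read_noise[win$rows, win$cols]
  bl <- gt$baseline[win$rows, win$cols]
  g <- gt$gain[win$rows, win$cols]
  npix <- roi_size^2
  sat <- saturation_level(gt)

  with_seed(seed, {
    photons <- if (photon_mode == "fixed") rep(emitter$photons, n_repeats)
    else {
      if (!is.function(photon_sampler)) {
        stop_arg("'photon_sampler' required for photon_mode = \"distribution\"")
      }
      photon_sampler(n_repeats)
    }
    # rate per pixel and repeat: ff * (N_r * E + bg) + DC * t
    rate <- as.vector(ff) * (outer(as.vector(E), photons) + emitter$bg) +
      as.vector(dc) * t
    n <- npix * n_repeats
    e <- stats::rpois(n, rate) + stats::rnorm(n, 0, as.vector(rn))
    adu <- round(as.vector(bl) + as.vector(g) * e)
    adu[adu < 0] <- 0
    adu[adu > sat] <- sat
    list(rois = array(adu, c(roi_size, roi_size, n_repeats)),
         rows = win$rows, cols = win$cols, origin = win$origin,
         truth = list(x = unname(emitter$x - win$origin["x"]),
                      y = unname(emitter$y - win$origin["y"]),
                      z = emitter$z, photons = emitter$photons,
                      bg = emitter$bg),
         photons = photons)
  })
}

# Crop derived maps to an ROI and convert to photoelectron-domain
# offset/variance/photon-response vectors.
crop_maps <- function(maps, rows, cols, uncorrected = FALSE) {
  off <- maps$offset[rows, cols]
  v <- maps$variance[rows, cols]
  pr <- maps$photon_response[rows, cols]
  if (uncorrected) {
    # field-averaged scalars in place of per-pixel maps
    off[] <- mean(maps$offset)
    v[] <- mean(maps$variance)
    pr[] <- mean(maps$photon_response)
  }
  list(offset = off, variance = v, photon_response = pr)
}

prep_fit_input <- function(rois, maps, rows = NULL, cols = NULL,
                           uncorrected = FALSE) {
  d3 <- dim(rois)
  nr <- d3[1]; nc <- d3[2]
  nrep <- if (length(d3) == 3L) d3[3] else 1L
  if (is.null(rows)) {
    if (!all(dim(maps$offset) == c(nr, nc))) {
      stop_arg("maps do not cover the ROI")
    }
    rows <- seq_len(nr); cols <- seq_len(nc)
  }
  cm <- crop_maps(maps, rows, cols, uncorrected)
  e <- (matrix(rois, nr * nc, nrep) - as.vector(cm$offset)) /
    as.vector(cm$photon_response)
  v <- pmax(0, as.vector(cm$variance)) / as.vector(cm$photon_response)^2
  list(d = e + v, v = v, nr = nr, nc = nc, nrep = nrep)
}

# Moment-based initialization from effective data; returns nrep x np matrix
# of (x_px, y_px, [z = 0,] N, bg). Background starts from the ROI border
# mean, position from the background-subtracted centroid.
init_estimates <- function(d, v, nr, nc, np) {
  e <- d - v
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE
  bg0 <- pmax(colMeans(e[as.vector(border), , drop = FALSE]), 0.01)
  w <- pmax(sweep(e, 2, bg0), 0)
  tot <- pmax(colSums(w), 1e-3)
  xs <- rep(seq_len(nc) - 0.5, each = nr)
  ys <- rep(seq_len(nr) - 0.5, times = nc)
  x0 <- colSums(w * xs) / tot
  y0 <- colSums(w * ys) / tot
  N0 <- pmax(colSums(e) - nr * nc * bg0, 10)
  if (np == 5L) cbind(x0, y0, 0, N0, bg0) else cbind(x0, y0, N0, bg0)
}

psf_par_vector <- function(psf) {
  c(psf$sigma0 / psf$pixel_size, psf$sigma0 / psf$pixel_size,
    psf$gamma %||% 0, psf$depth %||% 1, psf$A %||% 0, psf$B %||% 0)
}

#' Maximum-likelihood localization of a single emitter
#'
#' Fits emitter position, photon count and background to one ROI by
#' maximizing the per-pixel-variance-aware Poisson likelihood. The ADU data
#' are converted to photoelectrons with the per-pixel offset and photon
#' response maps; the per-pixel Gaussian noise variance (read noise plus
#' thermal noise at the map's exposure time, in photoelectron units
#' `v = variance / photon_response^2`) is folded into the Poisson
#' likelihood by shifting both data and model by `v`. Dark current is
#' thereby handled at the exposure time the maps were derived for: its mean
#' through the offset map, its Poisson variance through the variance map.
#'
#' With `corrected = FALSE` the per-pixel maps are replaced by their field
#' averages (a camera treated as homogeneous), which reproduces the biased
#' fitting that sCMOS-specific correction removes.
#'
#' @param roi matrix (or `rows x cols x n` array) of ADU counts.
#' @param maps a `derived_maps` object covering the ROI (crop with
#'   `rows`/`cols` if it covers the full camera).
#' @param psf a `psf_model`.
#' @param rows,cols optional camera-frame indices locating the ROI in
#'   full-camera maps.
#' @param init optional matrix of starting values (`n x np`:
#'   x, y\[, z\], N, bg; positions in pixels, ROI frame).
#' @param corrected use per-pixel maps (TRUE) or field-averaged scalars.
#' @param compute_crlb attach CRLB at the fitted parameters.
#' @param max_iter,tol_xy,tol_photons optimizer controls (iterations cap,
#'   convergence thresholds in pixels and photons).
#' @return An object of class `smlm_fit`: data.frame `estimates` with one
#'   row per frame (`x`, `y`, `z` (nm, ROI frame), `photons`, `bg`,
#'   `loglik`, `iterations`, `converged`) plus fields `crlb` (per-parameter
#'   variance bounds at the first frame's estimate) and `psf`.
#'   Non-convergence is flagged, never an error.
#' @export
mle_fit <- function(roi, maps, psf, rows = NULL, cols = NULL, init = NULL,
                    corrected = TRUE, compute_crlb = TRUE, max_iter = 50L,
                    tol_xy = 1e-4, tol_photons = 1e-2) {
  stopifnot(inherits(maps, "derived_maps"), inherits(psf, "psf_model"))
  if (!all(is.finite(roi))) stop_arg("'roi' must be finite")
  pin <- prep_fit_input(roi, maps, rows, cols, uncorrected = !corrected)
  astig <- psf$kind == "astigmatic3d"
  np <- if (astig) 5L else 4L
  if (is.null(init)) {
    init <- init_estimates(pin$d, pin$v, pin$nr, pin$nc, np)
  } else {
    init <- matrix(init, pin$nrep, np, byrow = is.null(dim(init)))
  }
  fit <- fit_mle_cpp(pin$d, pin$v, pin$nr, pin$nc, as.integer(astig),
                     psf_par_vector(psf), init, max_iter, tol_xy,
                     1e-2, tol_photons)
  px <- psf$pixel_size
  est <- data.frame(x = fit[, 1] * px, y = fit[, 2] * px)
  est$z <- if (astig) fit[, 3] else 0
  est$photons <- fit[, np - 1]
  est$bg <- fit[, np]
  est$loglik <- fit[, np + 1]
  est$iterations <- fit[, np + 2]
  est$converged <- fit[, np + 3] > 0

  cr <- NULL
  if (compute_crlb && est$converged[1]) {
    th <- list(x = est$x[1], y = est$y[1], N = est$photons[1], bg = est$bg[1])
    if (astig) th$z <- est$z[1]
    cr <- tryCatch(
      crlb(psf, th, matrix(pin$v, pin$nr, pin$nc), c(pin$nr, pin$nc)),
      error = function(e) NULL)
  }
  structure(list(estimates = est, crlb = cr, psf = psf,
                 corrected = corrected), class = "smlm_fit")
}

#' @export
print.smlm_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("MLE localization (%s, %s): %d frame(s), %d converged\n",
              x$psf$kind, if (x$corrected) "per-pixel maps" else
                "field-averaged maps", nrow(e), sum(e$converged)))
  cat(sprintf("  first frame: x = %.1f nm, y = %.1f nm, z = %.1f nm, N = %.0f, bg = %.1f\n",
              e$x[1], e$y[1], e$z[1], e$photons[1], e$bg[1]))
  if (!is.null(x$crlb)) {
    cat(sprintf("  sqrt-CRLB: x %.2f nm, y %.2f nm%s\n", sqrt(x$crlb[["x"]]),
                sqrt(x$crlb[["y"]]),
                if ("z" %in% names(x$crlb))
                  sprintf(", z %.2f nm", sqrt(x$crlb[["z"]])) else ""))
  }
  invisible(x)
}

#' @export
coef.smlm_fit <- function(object, ...) object$estimates
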