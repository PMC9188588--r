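# Photon-free camera calibration: orchestration and the fitted-model object.

#' Photon-free camera calibration from dark frames
#'
#' Fits the full per-pixel camera characterization from a series of dark
#' frame stacks acquired at several exposure times: per-pixel baseline and
#' dark current (mean vs. time), read noise squared and thermal noise
#' squared (variance vs. time), per-pixel gain and its global median
#' (variance vs. mean), and optionally a flatfield map from one bright
#' uniformly illuminated frame. No light is required for any step except
#' the optional flat-fielding.
#'
#' All fitted maps are stored in the ADU domain; electron-domain summaries
#' are derived through the median gain (`DC_e = DC_ADU / gain`,
#' `RN_e = sqrt(RN^2_ADU) / gain`).
#'
#' @param x an [exposure_series], a [pixel_statistics] result, or paths to
#'   per-exposure-time TIFF stacks (then `exposure_times` is required).
#' @param bright optional bright frame (matrix, ADU) for flat-fielding.
#' @param bright_exposure_time exposure time (s) of the bright frame, used
#'   to subtract the matching thermal offset; defaults to the shortest
#'   calibration exposure time.
#' @param exposure_times only for file-path input: seconds, one per file.
#' @param min_times minimum distinct exposure times (default 3).
#' @param min_range_sem gain-fit exclusion threshold, see
#'   [fit_variance_vs_mean].
#' @param smoothing_sigma flatfield illumination smoothing scale (pixels);
#'   default 1/8 of the short image dimension; `Inf` uses the global mean.
#' @return An object of class `camera_calibration` with per-pixel maps
#'   `baseline` (ADU), `dark_current_adu` (ADU/s), `read_noise_sq_adu`
#'   (ADU^2), `thermal_noise_sq_adu` (ADU^2/s), `gain` (ADU/e-, `NA` where
#'   indeterminate), scalar `median_gain`, `flatfield` (1 if no bright
#'   frame), `r2` (per-fit R^2 maps) and `diagnostics` (pixel flag counts,
#'   median R^2, electron-domain medians).
#' @seealso [predict.camera_calibration] / [derive_maps] for
#'   exposure-time-dependent offset, variance and photon-response maps.
#' @export
calibrate_camera <- function(x, bright = NULL, bright_exposure_time = NULL,
                             exposure_times = NULL, min_times = 3L,
                             min_range_sem = 5, smoothing_sigma = NULL) {
  stats <- if (inherits(x, "pixel_stats")) x else {
    pixel_statistics(x, exposure_times = exposure_times)
  }
  mfit <- tryCatch(fit_mean_vs_time(stats, min_times),
                   error = function(e) stop_arg("mean-vs-time fit: %s", conditionMessage(e)))
  vfit <- tryCatch(fit_variance_vs_time(stats, min_times),
                   error = function(e) stop_arg("variance-vs-time fit: %s", conditionMessage(e)))
  gfit <- tryCatch(fit_variance_vs_mean(stats, min_times, min_range_sem),
                   error = function(e) stop_arg("variance-vs-mean fit: %s", conditionMessage(e)))
  median_gain <- aggregate_gain(gfit$gain)

  shape <- dim(stats$mean)[1:2]
  cal <- structure(list(
    shape = shape,
    baseline = mfit$baseline,
    dark_current_adu = mfit$dark_current_adu,
    read_noise_sq_adu = vfit$read_noise_sq_adu,
    thermal_noise_sq_adu = vfit$thermal_noise_sq_adu,
    gain = gfit$gain,
    median_gain = median_gain,
    flatfield = matrix(1, shape[1], shape[2]),
    r2 = list(mean_vs_time = mfit$r2, variance_vs_time = vfit$r2,
              variance_vs_mean = gfit$r2),
    exposure_times = stats$exposure_times,
    n_frames = stats$n_frames
  ), class = "camera_calibration")

  if (!is.null(bright)) {
    t_b <- bright_exposure_time %||% min(stats$exposure_times)
    offset_b <- cal$baseline + cal$dark_current_adu * t_b
    cal$flatfield <- flatfield_from_bright(bright, offset_b,
                                           smoothing_sigma = smoothing_sigma)
  }

  cal$diagnostics <- list(
    n_negative_baseline = sum(cal$baseline < 0),
    n_negative_read_noise_sq = sum(cal$read_noise_sq_adu < 0),
    n_negative_dark_current = sum(cal$dark_current_adu < 0),
    n_missing_gain = sum(!is.finite(cal$gain)),
    median_r2 = vapply(cal$r2, stats::median, 0, na.rm = TRUE),
    dark_current_e_median = stats::median(cal$dark_current_adu) / median_gain,
    read_noise_e_median =
      stats::median(sqrt(pmax(0, cal$read_noise_sq_adu))) / median_gain
  )
  cal
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("Photon-free camera calibration (%d x %d px)\n",
              x$shape[1], x$shape[2]))
  cat(sprintf("  exposure times : %s ms (%s frames each)\n",
              paste(signif(1000 * x$exposure_times, 4), collapse = ", "),
              paste(unique(x$n_frames), collapse = "/")))
  cat(sprintf("  baseline       : median %.2f ADU\n", stats::median(x$baseline)))
  cat(sprintf("  dark current   : median %.2f ADU/s (%.2f e-/s)\n",
              stats::median(x$dark_current_adu),
              x$diagnostics$dark_current_e_median))
  cat(sprintf("  read noise     : median %.2f ADU rms (%.2f e-)\n",
              stats::median(sqrt(pmax(0, x$read_noise_sq_adu))),
              x$diagnostics$read_noise_e_median))
  cat(sprintf("  median gain    : %.3f ADU/e-\n", x$median_gain))
  invisible(x)
}

#' @export
summary.camera_calibration <- function(object, ...) {
  x <- object
  print(x)
  d <- x$diagnostics
  cat("Diagnostics:\n")
  cat(sprintf("  flagged pixels : %d negative baseline, %d negative read noise^2, %d missing gain\n",
              d$n_negative_baseline, d$n_negative_read_noise_sq,
              d$n_missing_gain))
  cat(sprintf("  median R^2     : mean~t %.4f, var~t %.4f, var~mean %.4f\n",
              d$median_r2[["mean_vs_time"]], d$median_r2[["variance_vs_time"]],
              d$median_r2[["variance_vs_mean"]]))
  invisible(x)
}

#' Median calibration parameters
#'
#' @param object a `camera_calibration`.
#' @param ... unused.
#' @return named vector of median parameters in ADU and electron domains.
#' @export
coef.camera_calibration <- function(object, ...) {
  c(baseline_adu = stats::median(object$baseline),
    dark_current_adu_per_s = stats::median(object$dark_current_adu),
    read_noise_sq_adu = stats::median(object$read_noise_sq_adu),
    thermal_noise_sq_adu_per_s = stats::median(object$thermal_noise_sq_adu),
    median_gain = object$median_gain,
    dark_current_e_per_s = object$diagnostics$dark_current_e_median,
    read_noise_e = object$diagnostics$read_noise_e_median)
}

#' Derived camera maps at one exposure time
#'
#' Materializes the exposure-time dependent maps consumed by sCMOS
#' correction and fitting algorithms: `offset = baseline +
#' dark_current_adu * t`, `variance = max(0, read_noise_sq + thermal_noise_sq
#' * t)` and `photon_response = median_gain * flatfield`. The variance floor
#' is applied here (negative fitted intercepts remain visible in the
#' calibration object itself).
#'
#' @param x a `camera_calibration` or a `camera_ground_truth` (the latter
#'   yields the exact maps implied by the simulator parameters).
#' @param exposure_time exposure time in seconds (>= 0).
#' @return A `derived_maps` object: list with `exposure_time`, `offset`
#'   (ADU), `variance` (ADU^2), `photon_response` (ADU/e-).
#' @export
derive_maps <- function(x, exposure_time) UseMethod("derive_maps")

#' @export
derive_maps.camera_calibration <- function(x, exposure_time) {
  if (exposure_time < 0) stop_arg("'exposure_time' must be >= 0")
  structure(list(
    exposure_time = exposure_time,
    offset = x$baseline + x$dark_current_adu * exposure_time,
    variance = pmax(x$read_noise_sq_adu +
                      x$thermal_noise_sq_adu * exposure_time, 0),
    photon_response = x$median_gain * x$flatfield
  ), class = "derived_maps")
}

#' @export
derive_maps.camera_ground_truth <- function(x, exposure_time) {
  if (exposure_time < 0) stop_arg("'exposure_time' must be >= 0")
  structure(list(
    exposure_time = exposure_time,
    offset = x$baseline + x$gain * x$dark_current * exposure_time,
    variance = x$gain^2 * (x$read_noise^2 + x$dark_current * exposure_time),
    photon_response = stats::median(x$gain) * x$flatfield
  ), class = "derived_maps")
}

#' Predict derived maps at an exposure time
#'
#' `predict(cal, exposure_time = t)` is the modelling-idiom spelling of
#' [derive_maps].
#' @param object a `camera_calibration`.
#' @param exposure_time exposure time in seconds.
#' @param ... unused.
#' @export
predict.camera_calibration <- function(object, exposure_time, ...) {
  derive_maps(object, exposure_time)
}

#' @export
print.derived_maps <- function(x, ...) {
  cat(sprintf("Derived camera maps at %.4g ms exposure time\n",
              1000 * x$exposure_time))
  cat(sprintf("  offset : median %.2f ADU   noise: median %.2f ADU rms   photon response: median %.3f ADU/e-\n",
              stats::median(x$offset), stats::median(sqrt(x$variance)),
              stats::median(x$photon_response)))
  invisible(x)
}

#' Display calibration maps
#'
#' @param x a `camera_calibration`.
#' @param which maps to draw.
#' @param ... passed to [graphics::image].
#' @export
plot.camera_calibration <- function(x, which = c("baseline",
                                                 "dark_current_adu",
                                                 "read_noise_sq_adu",
                                                 "gain"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  for (w in which) {
    m <- x[[w]]
    m[!is.finite(m)] <- stats::median(m, na.rm = TRUE)
    graphics::image(t(m)[, nrow(m):1], main = w, axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
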