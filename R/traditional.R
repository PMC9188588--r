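# Traditional varying-light-level calibration, used as the comparison
# baseline for the photon-free method.

#' Traditional camera calibration from varying light levels
#'
#' The conventional photon-transfer characterization at a single fixed
#' exposure time: offset and variance maps come from the dark stack (light
#' level zero) at that exposure time, and the per-pixel gain from the slope
#' of variance against mean across light levels (free intercept). Because
#' the dark stack already contains `DC*t` thermal electrons, this method
#' overestimates the true baseline and read noise by the thermal
#' contribution at the chosen exposure time — the error the photon-free
#' approach removes.
#'
#' @param level_stats list of per-level statistics (each a list with
#'   `mean`, `variance` matrices and `n`), ordered with the dark (zero
#'   light) level first; e.g. built from [simulate_light_stats].
#' @param light_levels numeric vector of nominal light levels (expected
#'   photoelectrons/pixel), same length; must include 0 and at least 3
#'   distinct values.
#' @return list of class `light_calibration` with `offset` (ADU),
#'   `variance` (ADU^2) from the dark level, `gain` map (ADU/e-),
#'   `median_gain`, and `exposure_time` if supplied via attribute.
#' @export
traditional_light_calibration <- function(level_stats, light_levels) {
  if (length(level_stats) != length(light_levels)) {
    stop_arg("one statistics entry per light level required")
  }
  if (length(unique(light_levels)) < 3L) {
    stop_arg("need at least 3 distinct light levels")
  }
  if (!any(light_levels == 0)) stop_arg("light levels must include darkness (0)")

  shape <- dim(level_stats[[1]]$mean)
  L <- length(light_levels)
  X <- matrix(0, prod(shape), L)
  Y <- matrix(0, prod(shape), L)
  for (i in seq_len(L)) {
    check_map(level_stats[[i]]$mean, shape, "mean")
    check_map(level_stats[[i]]$variance, shape, "variance")
    X[, i] <- level_stats[[i]]$mean
    Y[, i] <- level_stats[[i]]$variance
  }
  xb <- rowMeans(X); yb <- rowMeans(Y)
  Xc <- X - xb
  sxx <- rowSums(Xc * Xc)
  gain <- rowSums(Xc * (Y - yb)) / sxx
  gain[!is.finite(gain) | sxx <= 0] <- NA_real_

  dark <- which(light_levels == 0)[1]
  structure(list(
    offset = level_stats[[dark]]$mean,
    variance = level_stats[[dark]]$variance,
    gain = matrix(gain, shape[1], shape[2]),
    median_gain = aggregate_gain(matrix(gain, shape[1], shape[2])),
    light_levels = as.numeric(light_levels)
  ), class = "light_calibration")
}

#' @export
print.light_calibration <- function(x, ...) {
  cat(sprintf("Traditional light-level calibration (%d levels)\n",
              length(x$light_levels)))
  cat(sprintf("  offset: median %.2f ADU   noise: median %.2f ADU rms   median gain: %.3f ADU/e-\n",
              stats::median(x$offset), stats::median(sqrt(x$variance)),
              x$median_gain))
  invisible(x)
}
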