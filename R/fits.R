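# Per-pixel linear fits underlying the photon-free characterization.
#
# All three relations are straight lines fitted by the closed-form
# two-parameter ordinary-least-squares solution, vectorized over the pixel
# grid; no iterative solver is involved:
#   mean(t)     = BL + (g*DC) * t          -> baseline, dark current (ADU/s)
#   var(t)      = g^2*RN^2 + (g^2*DC) * t  -> read noise^2, thermal noise^2/s
#   var(mean)   = const + g * mean         -> gain (ADU/e-)

# Shared closed-form OLS of y (npix x T) on a common design x (length T).
ols_common_x <- function(Y, x) {
  xb <- mean(x)
  xc <- x - xb
  sxx <- sum(xc * xc)
  if (sxx <= 0) stop_arg("degenerate design: all predictor values identical")
  yb <- rowMeans(Y)
  slope <- as.vector(Y %*% xc) / sxx
  intercept <- yb - slope * xb
  fitted <- intercept + outer(slope, x)
  ss_res <- rowSums((Y - fitted)^2)
  ss_tot <- rowSums((Y - yb)^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  list(intercept = intercept, slope = slope, r2 = r2)
}

as_pixel_matrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, d[1] * d[2], d[3])
}

reshape_map <- function(v, shape) matrix(v, shape[1], shape[2])

check_stats_times <- function(stats, min_times) {
  if (!inherits(stats, "pixel_stats")) stop_arg("'stats' must be a pixel_stats")
  tt <- stats$exposure_times
  if (length(unique(tt)) < min_times) {
    stop_arg("need at least %d distinct exposure times", min_times)
  }
  tt
}

#' Fit per-pixel mean versus exposure time
#'
#' The y-intersect estimates the baseline (offset free of thermal effects,
#' ADU) and the slope the dark current in ADU per second.
#'
#' @param stats a [pixel_statistics] result.
#' @param min_times minimum number of distinct exposure times (default 3;
#'   two suffice for a line, three and more allow residual diagnostics).
#' @return list with matrices `baseline` (ADU), `dark_current_adu` (ADU/s)
#'   and `r2`.
#' @export
fit_mean_vs_time <- function(stats, min_times = 3L) {
  tt <- check_stats_times(stats, min_times)
  shape <- dim(stats$mean)[1:2]
  fit <- ols_common_x(as_pixel_matrix(stats$mean), tt)
  list(baseline = reshape_map(fit$intercept, shape),
       dark_current_adu = reshape_map(fit$slope, shape),
       r2 = reshape_map(fit$r2, shape))
}

#' Fit per-pixel variance versus exposure time
#'
#' The y-intersect estimates the read noise squared (ADU^2) and the slope
#' the thermal noise squared per second (ADU^2/s). Negative intercepts are
#' retained here (and flagged by [calibrate_camera]); they are floored at
#' zero only when derived variance maps are materialized.
#'
#' @inheritParams fit_mean_vs_time
#' @return list with matrices `read_noise_sq_adu` (ADU^2),
#'   `thermal_noise_sq_adu` (ADU^2/s) and `r2`.
#' @export
fit_variance_vs_time <- function(stats, min_times = 3L) {
  tt <- check_stats_times(stats, min_times)
  shape <- dim(stats$variance)[1:2]
  fit <- ols_common_x(as_pixel_matrix(stats$variance), tt)
  list(read_noise_sq_adu = reshape_map(fit$intercept, shape),
       thermal_noise_sq_adu = reshape_map(fit$slope, shape),
       r2 = reshape_map(fit$r2, shape))
}

#' Fit per-pixel variance versus mean: the gain
#'
#' Thermally generated electrons obey Poisson statistics, so across
#' exposure times the ADU variance is linear in the ADU mean with slope
#' equal to the pixel gain (ADU per electron). The intercept is left free:
#' read noise contributes an exposure-time-independent variance, so the
#' line does not pass through the origin.
#'
#' Pixels whose mean spans too small a range for a meaningful slope
#' (range < `min_range_sem` standard errors of the mean) are marked `NA`
#' and excluded from the gain median downstream.
#'
#' @inheritParams fit_mean_vs_time
#' @param min_range_sem exclusion threshold in units of the standard error
#'   of the per-time mean.
#' @return list with matrices `gain` (ADU/e-, `NA` where indeterminate) and
#'   `r2`.
#' @export
fit_variance_vs_mean <- function(stats, min_times = 3L, min_range_sem = 5) {
  check_stats_times(stats, min_times)
  shape <- dim(stats$mean)[1:2]
  X <- as_pixel_matrix(stats$mean)
  Y <- as_pixel_matrix(stats$variance)
  xb <- rowMeans(X)
  yb <- rowMeans(Y)
  Xc <- X - xb
  sxx <- rowSums(Xc * Xc)
  sxy <- rowSums(Xc * (Y - yb))
  gain <- sxy / sxx
  fitted_var <- yb + gain * Xc # residuals around per-pixel line
  ss_res <- rowSums((Y - yb - gain * Xc)^2)
  ss_tot <- rowSums((Y - yb)^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)

  # standard error of the mean at the widest time point, per pixel
  n <- max(stats$n_frames)
  sem <- sqrt(apply(Y, 1, max) / n)
  rng <- apply(X, 1, max) - apply(X, 1, min)
  bad <- !is.finite(gain) | sxx <= 0 | rng < min_range_sem * sem
  gain[bad] <- NA_real_
  list(gain = reshape_map(gain, shape), r2 = reshape_map(r2, shape))
}

#' Aggregate the per-pixel gain map into one global gain
#'
#' Single-pixel gain estimates from the few-electron regime are noisy, so
#' the global gain is the median over all valid pixels.
#'
#' @param gain_map matrix of per-pixel gains, `NA` for excluded pixels.
#' @return scalar median gain (ADU/e-).
#' @export
aggregate_gain <- function(gain_map) {
  g <- gain_map[is.finite(gain_map)]
  if (length(g) == 0L) stop_arg("no valid pixel gains to aggregate")
  stats::median(g)
}
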