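# Seeded validation experiments: hold-out map prediction, gain method
# comparison, and the thermal offset check.

#' The standard synthetic validation camera
#'
#' A versioned 64 x 64 fixture whose parameter distributions follow the
#' magnitudes of a characterized uncooled CMOS sensor: baseline near
#' 100 ADU with smooth structure, log-normal dark current (median
#' 25 e-/s) with 1% hot pixels at 10-50x the median, read noise 1-2 e-,
#' gain scattered around 2.2 ADU/e-, flatfield within about 2% of 1.
#'
#' @param seed integer seed fixing the fixture.
#' @param shape pixel grid.
#' @export
standard_fixture_camera <- function(seed = 1L, shape = c(64L, 64L)) {
  make_synthetic_camera(shape, hot_pixel_fraction = 0.01, seed = seed)
}

#' An uncooled industry-grade camera fixture
#'
#' Compared to the scientific-grade fixture, uncooled industry-grade CMOS
#' sensors show substantially higher dark current, hotter defect pixels and
#' higher read noise, which is where exposure-time-dependent correction
#' matters most for localization. This fixture uses a dark-current median
#' of 100 e-/s with 1% hot pixels at 50-200x the median and 2-4 e- read
#' noise; baseline, gain and flatfield scatter match the standard fixture.
#'
#' @inheritParams standard_fixture_camera
#' @export
industry_fixture_camera <- function(seed = 1L, shape = c(64L, 64L)) {
  make_synthetic_camera(shape, hot_pixel_fraction = 0.01,
                        parameter_ranges = list(
                          dark_current_median = 100,
                          dark_current_sdlog = 0.7,
                          hot_multiplier = c(50, 200),
                          read_noise_range = c(2, 4)),
                        seed = seed)
}

#' Choose a hot pixel with clearance for ROI-based experiments
#'
#' Returns the hot pixel nearest the camera center that keeps at least
#' `margin` pixels to every edge, so that localization ROIs around a grid
#' of neighboring emitters stay inside the frame.
#' @param gt a `camera_ground_truth` with hot pixels.
#' @param margin minimum distance to the camera edge (pixels).
#' @export
central_hot_pixel <- function(gt, margin = 12L) {
  hp <- gt$hot_pixels
  ok <- hp[, 1] > margin & hp[, 1] <= gt$shape[1] - margin &
    hp[, 2] > margin & hp[, 2] <= gt$shape[2] - margin
  hp <- hp[ok, , drop = FALSE]
  if (nrow(hp) == 0L) stop_arg("no hot pixel with sufficient edge clearance")
  ctr <- gt$shape / 2
  hp[which.min((hp[, 1] - ctr[1])^2 + (hp[, 2] - ctr[2])^2), ]
}

#' Hold-out validation of predicted offset and noise maps
#'
#' Calibrates the camera photon-free on `calib_times`, predicts the
#' per-pixel offset and noise maps at held-out exposure times, then
#' measures offset and noise directly from freshly simulated dark stacks at
#' those times. Reported per held-out time: the mean over pixels of
#' `|predicted - measured| / measured * 100`, separately for the mean
#' (offset) and the standard deviation (noise); the headline numbers
#' average over pixels first, then over held-out times.
#'
#' With `analytic = TRUE` both the calibration statistics and the held-out
#' measurements use the exact model moments instead of sampled frames — a
#' self-consistency check that must give errors near zero.
#'
#' @param gt a `camera_ground_truth`.
#' @param calib_times calibration exposure times (s).
#' @param holdout_times held-out exposure times (s), disjoint from
#'   `calib_times`.
#' @param n_frames frames per exposure time (calibration and measurement).
#' @param seed integer seed.
#' @param analytic use exact moments instead of simulation.
#' @return A `validation_report` list: `per_time` data.frame
#'   (`exposure_time`, `offset_error_pct`, `noise_error_pct`),
#'   `offset_error_pct`, `noise_error_pct` (averages over times),
#'   `calibration`, and the configuration (`n_frames`, `seed`).
#' @export
holdout_map_validation <- function(gt, calib_times, holdout_times, n_frames,
                                   seed = NULL, analytic = FALSE) {
  stopifnot(inherits(gt, "camera_ground_truth"))
  if (length(intersect(calib_times, holdout_times)) > 0L) {
    stop_arg("held-out exposure times must be disjoint from calibration times")
  }
  moments_at <- function(t, k) {
    if (analytic) c(expected_dark_moments(gt, t), list(n = Inf))
    else simulate_dark_stats(gt, t, n_frames, seed = child_seed(seed, k))
  }
  mom <- lapply(seq_along(calib_times), function(i) moments_at(calib_times[i], i))
  stats <- pixel_stats_from_moments(
    calib_times, lapply(mom, `[[`, "mean"), lapply(mom, `[[`, "variance"),
    if (analytic) 1e9 else n_frames)
  cal <- calibrate_camera(stats)

  per_time <- lapply(seq_along(holdout_times), function(j) {
    t <- holdout_times[j]
    pred <- derive_maps(cal, t)
    meas <- moments_at(t, 1000L + j)
    data.frame(
      exposure_time = t,
      offset_error_pct = 100 * mean(abs(pred$offset - meas$mean) / meas$mean),
      noise_error_pct = 100 * mean(abs(sqrt(pred$variance) -
                                         sqrt(meas$variance)) /
                                     sqrt(meas$variance)))
  })
  per_time <- do.call(rbind, per_time)
  structure(list(per_time = per_time,
                 offset_error_pct = mean(per_time$offset_error_pct),
                 noise_error_pct = mean(per_time$noise_error_pct),
                 calibration = cal, n_frames = n_frames, seed = seed,
                 analytic = analytic),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Hold-out map validation\n")
  for (i in seq_len(nrow(x$per_time))) {
    cat(sprintf("  %6.1f ms: offset error %.3f%%, noise error %.3f%%\n",
                1000 * x$per_time$exposure_time[i],
                x$per_time$offset_error_pct[i], x$per_time$noise_error_pct[i]))
  }
  cat(sprintf("  average  : offset %.3f%%, noise %.3f%%\n",
              x$offset_error_pct, x$noise_error_pct))
  invisible(x)
}

#' Compare photon-free and varying-light-level gain estimates
#'
#' Runs both calibrations on the same synthetic camera and reports the
#' median gains and their relative deviation, plus each method's deviation
#' from the simulator's true median gain.
#'
#' @param gt a `camera_ground_truth`.
#' @param calib_times photon-free calibration exposure times (s).
#' @param light_levels photoelectron levels for the traditional method
#'   (must include 0).
#' @param t_light fixed exposure time for the traditional method (s).
#' @param n_frames frames per exposure time / light level.
#' @param seed integer seed.
#' @return list with `median_gain_photon_free`, `median_gain_light`,
#'   `deviation_pct` (relative to the light-level method),
#'   `true_median_gain` and per-method truth deviations (%).
#' @export
gain_method_comparison <- function(gt, calib_times, light_levels = c(0, 200,
                                   500, 1000, 2000), t_light = 0.01,
                                   n_frames = 5000L, seed = NULL) {
  stopifnot(inherits(gt, "camera_ground_truth"))
  mom <- lapply(seq_along(calib_times), function(i) {
    simulate_dark_stats(gt, calib_times[i], n_frames,
                        seed = child_seed(seed, i))
  })
  stats <- pixel_stats_from_moments(calib_times, lapply(mom, `[[`, "mean"),
                                    lapply(mom, `[[`, "variance"), n_frames)
  cal <- calibrate_camera(stats)

  level_stats <- lapply(seq_along(light_levels), function(i) {
    simulate_light_stats(gt, light_levels[i], t_light, n_frames,
                         seed = child_seed(seed, 2000L + i))
  })
  trad <- traditional_light_calibration(level_stats, light_levels)

  g_true <- stats::median(gt$gain)
  list(median_gain_photon_free = cal$median_gain,
       median_gain_light = trad$median_gain,
       deviation_pct = 100 * abs(cal$median_gain - trad$median_gain) /
         trad$median_gain,
       true_median_gain = g_true,
       photon_free_vs_truth_pct = 100 * abs(cal$median_gain - g_true) / g_true,
       light_vs_truth_pct = 100 * abs(trad$median_gain - g_true) / g_true,
       calibration = cal, traditional = trad, seed = seed)
}

#' Mean thermal offset increase at an exposure time
#'
#' The field-averaged difference between the dark-frame mean at exposure
#' time `t` and the true baseline; equals `mean(gain * DC) * t` up to
#' sampling error. This is the amount by which a fixed-exposure
#' characterization overestimates the baseline.
#'
#' @param gt a `camera_ground_truth`.
#' @param t exposure time (s).
#' @param n_frames frames to average (use `Inf` for the analytic value).
#' @param seed integer seed.
#' @return scalar ADU.
#' @export
thermal_offset_check <- function(gt, t, n_frames = 2000L, seed = NULL) {
  stopifnot(inherits(gt, "camera_ground_truth"), t >= 0)
  m <- if (is.infinite(n_frames)) expected_dark_moments(gt, t)$mean
  else simulate_dark_stats(gt, t, n_frames, seed = seed)$mean
  mean(m - gt$baseline)
}
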