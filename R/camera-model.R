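# Parametric per-pixel camera model and synthetic frame generators.
#
# The model for a dark frame at exposure time t (seconds) is, per pixel k:
#
#   ADU_k = clip(round(BL_k + g_k * (Poisson(DC_k * t) + Normal(0, RN_k))),
#                0, 2^bit_depth - 1)
#
# with baseline BL (ADU), gain g (ADU/electron), dark current DC
# (electrons/s) and Gaussian read noise RN (electrons, sd). Thermal noise is
# not an independent parameter: dark-current electrons are Poisson, so their
# variance per second equals DC itself. Bright frames add
# Poisson(flatfield_k * photons) photoelectrons before gain conversion.

#' Construct a synthetic camera ground truth
#'
#' Generates per-pixel parameter maps emulating a CMOS sensor: a smoothly
#' varying baseline, log-normal dark current with a designated fraction of
#' "hot" pixels (dark current at least 10x the median), per-pixel gain
#' scattered around a global value, Gaussian read noise, and a flatfield
#' (relative sensitivity) map close to 1.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param hot_pixel_fraction fraction of pixels turned into hot pixels
#'   (dark current multiplied by a factor drawn from `hot_multiplier`).
#' @param parameter_ranges optional list overriding any of: `baseline_mean`
#'   (ADU), `baseline_amplitude` (ADU, smooth variation), `baseline_jitter`
#'   (ADU sd), `dark_current_median` (e-/s), `dark_current_sdlog`,
#'   `hot_multiplier` (length-2 range), `read_noise_range` (e-, length-2),
#'   `gain_mean` (ADU/e-), `gain_sd`, `flatfield_sd`, `bit_depth`.
#' @param seed integer seed; identical seeds give identical cameras.
#' @param hot_read_noise if TRUE, hot pixels also receive elevated read
#'   noise (3x); by default defects are dark-current only.
#' @return An object of class `camera_ground_truth` with fields `shape`,
#'   `baseline`, `dark_current`, `read_noise`, `gain`, `flatfield`,
#'   `bit_depth` and `hot_pixels` (n x 2 matrix of row/col indices).
#' @export
make_synthetic_camera <- function(shape, hot_pixel_fraction = 0.01,
                                  parameter_ranges = list(), seed = NULL,
                                  hot_read_noise = FALSE) {
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape))) {
    stop_arg("'shape' must be two positive integers")
  }
  if (!is.numeric(hot_pixel_fraction) || hot_pixel_fraction < 0 ||
      hot_pixel_fraction >= 1) {
    stop_arg("'hot_pixel_fraction' must be in [0, 1)")
  }
  p <- utils::modifyList(list(
    baseline_mean = 100, baseline_amplitude = 2, baseline_jitter = 0.5,
    dark_current_median = 25, dark_current_sdlog = 0.5,
    hot_multiplier = c(10, 50),
    read_noise_range = c(1, 2),
    gain_mean = 2.2, gain_sd = 0.05,
    flatfield_sd = 0.02, bit_depth = 16L
  ), parameter_ranges)
  if (p$gain_mean <= 0 || p$dark_current_median < 0) {
    stop_arg("parameter ranges must be positive")
  }
  shape <- as.integer(shape)
  nr <- shape[1]; nc <- shape[2]; npix <- nr * nc

  with_seed(seed, {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    baseline <- p$baseline_mean +
      p$baseline_amplitude * sin(2 * pi * rr / nr) * cos(2 * pi * cc / nc) +
      matrix(stats::rnorm(npix, 0, p$baseline_jitter), nr, nc)

    dc <- if (p$dark_current_median == 0) matrix(0, nr, nc) else {
      matrix(stats::rlnorm(npix, log(p$dark_current_median),
                           p$dark_current_sdlog), nr, nc)
    }
    n_hot <- round(hot_pixel_fraction * npix)
    hot <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    if (n_hot > 0) {
      idx <- sample.int(npix, n_hot)
      # multipliers apply to the realized map median; a final floor keeps
      # every flagged pixel at >= 10x the full-map median even after the
      # hot values themselves nudge that median upward
      dc[idx] <- stats::median(dc) *
        stats::runif(n_hot, p$hot_multiplier[1], p$hot_multiplier[2])
      dc[idx] <- pmax(dc[idx], 10 * stats::median(dc))
      hot <- cbind(row = ((idx - 1L) %% nr) + 1L,
                   col = ((idx - 1L) %/% nr) + 1L)
    }

    rn <- matrix(stats::runif(npix, p$read_noise_range[1],
                              p$read_noise_range[2]), nr, nc)
    if (hot_read_noise && n_hot > 0) rn[hot] <- rn[hot] * 3

    gain <- matrix(pmax(0.1, stats::rnorm(npix, p$gain_mean, p$gain_sd)),
                   nr, nc)
    ff <- matrix(pmax(0.5, stats::rnorm(npix, 1, p$flatfield_sd)), nr, nc)
    ff <- ff / stats::median(ff)

    structure(list(
      shape = shape, baseline = baseline, dark_current = dc,
      read_noise = rn, gain = gain, flatfield = ff,
      bit_depth = as.integer(p$bit_depth), hot_pixels = hot
    ), class = "camera_ground_truth")
  })
}

#' @export
print.camera_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic camera ground truth: %d x %d pixels, %d-bit\n",
              x$shape[1], x$shape[2], x$bit_depth))
  cat(sprintf("  baseline     : median %.1f ADU\n", stats::median(x$baseline)))
  cat(sprintf("  dark current : median %.1f e-/s, %d hot pixel(s)\n",
              stats::median(x$dark_current), nrow(x$hot_pixels)))
  cat(sprintf("  read noise   : median %.2f e-\n", stats::median(x$read_noise)))
  cat(sprintf("  gain         : median %.3f ADU/e-\n", stats::median(x$gain)))
  invisible(x)
}

saturation_level <- function(gt) 2^gt$bit_depth - 1

# Core noise model: one npix x n_frames matrix of quantized, clipped ADU.
# extra_rate: additional Poisson photoelectron rate per pixel (e.g. light).
sim_adu_chunk <- function(gt, t, n_frames, extra_rate = 0) {
  npix <- prod(gt$shape)
  lambda <- as.vector(gt$dark_current) * t + extra_rate
  n <- npix * n_frames
  e <- stats::rpois(n, lambda) + stats::rnorm(n, 0, as.vector(gt$read_noise))
  adu <- round(as.vector(gt$baseline) + as.vector(gt$gain) * e)
  dim(adu) <- c(npix, n_frames)
  adu[adu < 0] <- 0
  sat <- saturation_level(gt)
  adu[adu > sat] <- sat
  adu
}

#' Simulate a stack of dark frames
#'
#' @param gt a `camera_ground_truth`.
#' @param t exposure time in seconds.
#' @param n_frames number of frames.
#' @param seed optional integer seed.
#' @return integer-valued array `rows x cols x n_frames` of ADU counts.
#' @export
simulate_dark_frames <- function(gt, t, n_frames = 1L, seed = NULL) {
  stopifnot(inherits(gt, "camera_ground_truth"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop_arg("'t' must be a single non-negative exposure time in seconds")
  }
  if (n_frames < 1) stop_arg("'n_frames' must be >= 1")
  with_seed(seed, {
    m <- sim_adu_chunk(gt, t, n_frames)
    array(m, c(gt$shape, n_frames))
  })
}

#' Expected dark-frame moments (no sampling)
#'
#' Analytic per-pixel mean and variance of the dark-frame model at exposure
#' time `t`, ignoring quantization and clipping: mean `BL + g*DC*t`,
#' variance `g^2 * (RN^2 + DC*t)`.
#' @inheritParams simulate_dark_frames
#' @return list with `mean` and `variance` matrices (ADU, ADU^2).
#' @export
expected_dark_moments <- function(gt, t) {
  stopifnot(inherits(gt, "camera_ground_truth"), t >= 0)
  list(mean = gt$baseline + gt$gain * gt$dark_current * t,
       variance = gt$gain^2 * (gt$read_noise^2 + gt$dark_current * t))
}

#' Streaming per-pixel statistics of freshly simulated dark frames
#'
#' Simulates `n_frames` dark frames at exposure time `t` in chunks and
#' accumulates per-pixel mean and unbiased variance without holding the
#' stack in memory. Statistically identical to
#' `pixel_statistics(simulate_dark_frames(...))` for matched seeds policies.
#'
#' @inheritParams simulate_dark_frames
#' @param chunk frames simulated per chunk.
#' @return list with `mean`, `variance` (matrices) and `n`.
#' @export
simulate_dark_stats <- function(gt, t, n_frames, seed = NULL, chunk = 512L) {
  stopifnot(inherits(gt, "camera_ground_truth"), t >= 0, n_frames >= 2)
  with_seed(seed, {
    acc <- stat_accumulator(prod(gt$shape))
    left <- n_frames
    while (left > 0) {
      f <- min(chunk, left)
      acc <- stat_update(acc, sim_adu_chunk(gt, t, f))
      left <- left - f
    }
    out <- stat_finalize(acc)
    list(mean = matrix(out$mean, gt$shape[1], gt$shape[2]),
         variance = matrix(out$variance, gt$shape[1], gt$shape[2]),
         n = out$n)
  })
}

#' Simulate a series of dark-frame stacks at several exposure times
#'
#' Emulates the nested acquisition protocol used for photon-free
#' calibration: in `"nested"` order the exposure time changes after every
#' frame and the whole cycle repeats, keeping the mean thermal load constant
#' on real hardware. The model has no temperature drift, so nested and
#' blocked schedules are statistically equivalent here.
#'
#' @param gt a `camera_ground_truth`.
#' @param exposure_times at least 3 distinct exposure times (seconds).
#' @param n_per_time frames per exposure time.
#' @param seed optional integer seed.
#' @param schedule `"nested"` (round-robin) or `"blocked"`.
#' @return An `exposure_series`: list with `exposure_times`, `frames` (one
#'   `rows x cols x n_per_time` array per time), `schedule`, `bit_depth`.
#' @export
simulate_dark_series <- function(gt, exposure_times, n_per_time, seed = NULL,
                                 schedule = c("nested", "blocked")) {
  stopifnot(inherits(gt, "camera_ground_truth"))
  schedule <- match.arg(schedule)
  tt <- as.numeric(exposure_times)
  if (length(unique(tt)) < 3L) stop_arg("need at least 3 distinct exposure times")
  if (any(tt < 0)) stop_arg("exposure times must be non-negative")
  nr <- gt$shape[1]; nc <- gt$shape[2]; npix <- nr * nc

  with_seed(seed, {
    frames <- lapply(tt, function(.) array(0, c(nr, nc, n_per_time)))
    if (schedule == "nested") {
      for (r in seq_len(n_per_time)) {
        for (i in seq_along(tt)) {
          frames[[i]][, , r] <- sim_adu_chunk(gt, tt[i], 1L)
        }
      }
    } else {
      for (i in seq_along(tt)) {
        frames[[i]] <- array(sim_adu_chunk(gt, tt[i], n_per_time),
                             c(nr, nc, n_per_time))
      }
    }
    exposure_series(tt, frames, schedule, gt$bit_depth)
  })
}

#' Assemble an exposure series from frame stacks
#'
#' @param exposure_times exposure times in seconds, one per stack.
#' @param frames list of `rows x cols x n` arrays (ADU), equal frame counts.
#' @param schedule acquisition order tag.
#' @param bit_depth camera bit depth.
#' @export
exposure_series <- function(exposure_times, frames,
                            schedule = c("nested", "blocked"),
                            bit_depth = 16L) {
  schedule <- match.arg(schedule)
  if (length(exposure_times) != length(frames)) {
    stop_arg("one frame stack per exposure time required")
  }
  dims <- lapply(frames, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1L) {
    stop_arg("all frames must share the same shape")
  }
  ns <- vapply(dims, function(d) if (length(d) == 3L) d[3] else 1L, 0)
  if (length(unique(ns)) != 1L) {
    stop_arg("each exposure time must have the same frame count")
  }
  sat <- 2^bit_depth - 1
  for (f in frames) {
    if (min(f) < 0 || max(f) > sat) stop_arg("ADU values outside [0, saturation]")
  }
  structure(list(exposure_times = as.numeric(exposure_times), frames = frames,
                 schedule = schedule, bit_depth = as.integer(bit_depth)),
            class = "exposure_series")
}

#' @export
print.exposure_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Exposure series: %d exposure times (%s ms), %d frames each, %d x %d px, %s schedule\n",
    length(x$exposure_times),
    paste(signif(1000 * x$exposure_times, 4), collapse = ", "),
    if (length(d) == 3L) d[3] else 1L, d[1], d[2], x$schedule))
  invisible(x)
}

#' Simulate bright (uniformly illuminated) frames
#'
#' Adds `Poisson(flatfield_k * photons * profile_k)` photoelectrons on top of
#' the dark-frame model before gain conversion. The illumination profile
#' (default uniform) multiplies the photon rate, e.g. to emulate vignetting.
#'
#' @inheritParams simulate_dark_frames
#' @param photons_per_pixel expected photoelectrons per pixel (at
#'   flatfield = 1, profile = 1).
#' @param illumination_profile optional matrix multiplying the photon rate.
#' @return array `rows x cols x n_frames` of ADU counts.
#' @export
simulate_bright_frames <- function(gt, photons_per_pixel,
                                   illumination_profile = NULL, t = 0,
                                   n_frames = 1L, seed = NULL) {
  stopifnot(inherits(gt, "camera_ground_truth"))
  if (photons_per_pixel < 0) stop_arg("'photons_per_pixel' must be >= 0")
  if (t < 0) stop_arg("'t' must be >= 0")
  profile <- illumination_profile %||% 1
  if (is.matrix(profile)) check_map(profile, gt$shape, "illumination_profile")
  rate <- as.vector(gt$flatfield) * photons_per_pixel * as.vector(profile)
  with_seed(seed, {
    m <- sim_adu_chunk(gt, t, n_frames, extra_rate = rate)
    array(m, c(gt$shape, n_frames))
  })
}

#' Streaming statistics of simulated uniformly illuminated frames
#'
#' @inheritParams simulate_bright_frames
#' @param chunk frames per simulation chunk.
#' @return list with `mean`, `variance`, `n`.
#' @export
simulate_light_stats <- function(gt, photons_per_pixel, t, n_frames,
                                 seed = NULL, chunk = 512L) {
  stopifnot(inherits(gt, "camera_ground_truth"), n_frames >= 2)
  rate <- as.vector(gt$flatfield) * photons_per_pixel
  with_seed(seed, {
    acc <- stat_accumulator(prod(gt$shape))
    left <- n_frames
    while (left > 0) {
      f <- min(chunk, left)
      acc <- stat_update(acc, sim_adu_chunk(gt, t, f, extra_rate = rate))
      left <- left - f
    }
    out <- stat_finalize(acc)
    list(mean = matrix(out$mean, gt$shape[1], gt$shape[2]),
         variance = matrix(out$variance, gt$shape[1], gt$shape[2]),
         n = out$n)
  })
}
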