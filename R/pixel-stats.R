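# Per-pixel statistics over an exposure series.

#' Per-pixel mean and variance for each exposure time
#'
#' Computes, for every exposure time of the series, the per-pixel mean and
#' unbiased (n-1) variance over frames. The computation is chunked so that
#' only a bounded number of frames is resident at a time; `x` may be an
#' in-memory [exposure_series] or a character vector of multi-page TIFF
#' stacks (one per exposure time), which are read page-wise.
#'
#' @param x an `exposure_series`, or character paths to TIFF stacks.
#' @param exposure_times required when `x` is a character vector: exposure
#'   times in seconds, one per file.
#' @param chunk frames processed per chunk.
#' @return A `pixel_stats` object: list with `exposure_times`, `mean` and
#'   `variance` (`rows x cols x n_times` arrays), `n_frames`.
#' @export
pixel_statistics <- function(x, exposure_times = NULL, chunk = 256L) {
  if (inherits(x, "exposure_series")) {
    tt <- x$exposure_times
    stacks <- x$frames
    get_stat <- function(i) {
      f <- stacks[[i]]
      d <- dim(f)
      if (length(d) != 3L || d[3] < 2L) stop_arg("need >= 2 frames per exposure time")
      npix <- d[1] * d[2]
      acc <- stat_accumulator(npix)
      for (s in seq(1L, d[3], by = chunk)) {
        e <- min(d[3], s + chunk - 1L)
        m <- f[, , s:e, drop = FALSE]
        dim(m) <- c(npix, e - s + 1L)
        acc <- stat_update(acc, m)
      }
      c(stat_finalize(acc), list(shape = d[1:2]))
    }
    n_times <- length(tt)
  } else if (is.character(x)) {
    if (is.null(exposure_times) || length(exposure_times) != length(x)) {
      stop_arg("'exposure_times' must accompany file paths, one per file")
    }
    tt <- as.numeric(exposure_times)
    get_stat <- function(i) {
      np <- count_tiff_pages(x[i])
      if (np < 2L) stop_arg("need >= 2 frames per exposure time")
      first <- read_stack(x[i], pages = 1L)
      shape <- dim(first)[1:2]
      acc <- stat_accumulator(prod(shape))
      for (s in seq(1L, np, by = chunk)) {
        e <- min(np, s + chunk - 1L)
        m <- read_stack(x[i], pages = s:e)
        if (!all(dim(m)[1:2] == shape)) stop_arg("mixed page shapes in '%s'", x[i])
        dim(m) <- c(prod(shape), e - s + 1L)
        acc <- stat_update(acc, m)
      }
      c(stat_finalize(acc), list(shape = shape))
    }
    n_times <- length(x)
  } else {
    stop_arg("'x' must be an exposure_series or a character vector of paths")
  }

  res <- lapply(seq_len(n_times), get_stat)
  shape <- res[[1]]$shape
  for (r in res) {
    if (!all(r$shape == shape)) stop_arg("mismatched frame shapes across exposure times")
  }
  mean_arr <- array(0, c(shape, n_times))
  var_arr <- array(0, c(shape, n_times))
  for (i in seq_len(n_times)) {
    mean_arr[, , i] <- res[[i]]$mean
    var_arr[, , i] <- res[[i]]$variance
  }
  structure(list(exposure_times = tt, mean = mean_arr, variance = var_arr,
                 n_frames = vapply(res, `[[`, 0, "n")),
            class = "pixel_stats")
}

#' Assemble a pixel_stats object from precomputed moments
#'
#' Useful when means/variances are produced by streaming simulation
#' ([simulate_dark_stats]) or read from projection images.
#' @param exposure_times exposure times (seconds).
#' @param means,variances lists of per-pixel matrices, one per time.
#' @param n_frames frames per time (scalar or vector).
#' @export
pixel_stats_from_moments <- function(exposure_times, means, variances,
                                     n_frames) {
  stopifnot(length(exposure_times) == length(means),
            length(means) == length(variances))
  shape <- dim(means[[1]])
  mean_arr <- array(0, c(shape, length(means)))
  var_arr <- array(0, c(shape, length(means)))
  for (i in seq_along(means)) {
    check_map(means[[i]], shape, "means")
    check_map(variances[[i]], shape, "variances")
    mean_arr[, , i] <- means[[i]]
    var_arr[, , i] <- variances[[i]]
  }
  structure(list(exposure_times = as.numeric(exposure_times),
                 mean = mean_arr, variance = var_arr,
                 n_frames = rep_len(n_frames, length(means))),
            class = "pixel_stats")
}

#' @export
print.pixel_stats <- function(x, ...) {
  d <- dim(x$mean)
  cat(sprintf("Pixel statistics: %d x %d px at %d exposure times (%s ms)\n",
              d[1], d[2], length(x$exposure_times),
              paste(signif(1000 * x$exposure_times, 4), collapse = ", ")))
  invisible(x)
}
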