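# Flat-fielding from a single bright, homogeneously illuminated frame.

#' Flatfield map from a bright frame
#'
#' Estimates per-pixel relative sensitivity from one (or an average of
#' several) uniformly illuminated frame(s). The offset-subtracted signal is
#' divided by a heavily smoothed copy of itself, which captures the
#' illumination profile (e.g. gentle vignetting) while leaving
#' pixel-to-pixel sensitivity variation in the quotient; the result is
#' normalized to median 1. With perfectly uniform illumination the smoothed
#' field reduces to the global mean.
#'
#' @param bright matrix of ADU values (average several frames to suppress
#'   shot noise).
#' @param offset per-pixel offset map (ADU) at the bright frame's exposure
#'   time.
#' @param smoothing_sigma Gaussian smoothing scale in pixels; default 1/8 of
#'   the short image dimension; `Inf` divides by the global mean.
#' @param saturation ADU level treated as saturated (default `2^16 - 1`).
#' @return flatfield matrix, median 1.
#' @export
flatfield_from_bright <- function(bright, offset, smoothing_sigma = NULL,
                                  saturation = 65535) {
  if (!is.matrix(bright)) stop_arg("'bright' must be a matrix")
  check_map(offset, dim(bright), "offset")
  if (mean(bright >= saturation) > 0.01) {
    stop_arg("bright frame saturated at > 1%% of pixels")
  }
  signal <- bright - offset
  if (stats::median(signal) <= 100) {
    stop_arg("bright frame too dim: median offset-subtracted signal must exceed 100 ADU")
  }
  smoothing_sigma <- smoothing_sigma %||% (min(dim(bright)) / 8)
  illum <- if (is.infinite(smoothing_sigma)) {
    matrix(mean(signal), nrow(signal), ncol(signal))
  } else {
    gaussian_smooth(signal, smoothing_sigma)
  }
  ff <- signal / illum
  ff / stats::median(ff)
}

# Large-kernel Gaussian smoothing with replicated (edge-extended) boundary.
gaussian_smooth <- function(x, sigma) {
  f <- EBImage::makeBrush(2L * ceiling(3 * sigma) + 1L, shape = "Gaussian",
                          sigma = sigma)
  as.matrix(EBImage::filter2(x, f, boundary = "replicate"))
}
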