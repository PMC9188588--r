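# Point-spread-function models: integrated 2D Gaussian and parametric
# astigmatic 3D Gaussian, plus Fisher-information / CRLB machinery.
#
# Coordinate convention (asserted by the symmetry regression test): ROI
# pixels are unit squares in a 0-based frame, pixel (i, j) spanning
# [j, j+1] x [i, i+1] with its center at (j + 0.5, i + 0.5); x runs along
# columns, y along rows. Physical positions in nm map to pixels through
# `pixel_size`.

#' 2D Gaussian PSF model
#'
#' @param sigma0 in-focus Gaussian width (nm, sd).
#' @param pixel_size projected camera pixel width (nm); default 98.
#' @return object of class `psf_model`, kind `"gauss2d"`.
#' @export
psf_gauss2d <- function(sigma0 = 127, pixel_size = 98) {
  if (sigma0 <= 0 || pixel_size <= 0) stop_arg("sigma0 and pixel_size must be > 0")
  structure(list(kind = "gauss2d", sigma0 = sigma0, pixel_size = pixel_size),
            class = "psf_model")
}

#' Astigmatic 3D Gaussian PSF model
#'
#' Axial position is encoded in the x/y ellipticity introduced by a
#' cylindrical lens. Per axis,
#' `sigma_x(z) = sigma0 * sqrt(1 + u^2 + A u^3 + B u^4)` with
#' `u = (z - gamma)/d`, and `sigma_y` the mirror image (`z + gamma`), so
#' the two widths cross at `z = 0`.
#'
#' @param sigma0 in-focus width (nm, sd).
#' @param pixel_size projected pixel width (nm).
#' @param gamma focal-plane offset per axis (nm).
#' @param depth depth scale d (nm).
#' @param A,B higher-order coefficients (dimensionless).
#' @export
psf_astigmatic3d <- function(sigma0 = 127, pixel_size = 98, gamma = 250,
                             depth = 400, A = 0, B = 0) {
  if (sigma0 <= 0 || pixel_size <= 0 || depth <= 0) {
    stop_arg("sigma0, pixel_size and depth must be > 0")
  }
  structure(list(kind = "astigmatic3d", sigma0 = sigma0,
                 pixel_size = pixel_size, gamma = gamma, depth = depth,
                 A = A, B = B),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("PSF model '%s': sigma0 = %.0f nm, pixel %.0f nm", x$kind,
              x$sigma0, x$pixel_size))
  if (x$kind == "astigmatic3d") {
    cat(sprintf(", gamma = %.0f nm, depth = %.0f nm, A = %g, B = %g",
                x$gamma, x$depth, x$A, x$B))
  }
  cat("\n")
  invisible(x)
}

#' PSF widths at an axial position
#'
#' @param psf a `psf_model`.
#' @param z axial position(s), nm (ignored for 2D).
#' @return list with `sx`, `sy` (nm) and derivatives `dsx`, `dsy` (nm/nm).
#' @export
psf_sigma <- function(psf, z = 0) {
  if (psf$kind == "gauss2d") {
    one <- rep(1, length(z))
    return(list(sx = psf$sigma0 * one, sy = psf$sigma0 * one,
                dsx = 0 * one, dsy = 0 * one))
  }
  sig <- function(z, gamma) {
    u <- (z - gamma) / psf$depth
    s2 <- 1 + u^2 + psf$A * u^3 + psf$B * u^4
    if (any(s2 <= 0)) stop_arg("PSF width undefined (sigma^2 <= 0) at this z")
    s <- psf$sigma0 * sqrt(s2)
    ds <- psf$sigma0^2 * (2 * u + 3 * psf$A * u^2 + 4 * psf$B * u^3) /
      (2 * s * psf$depth)
    list(s = s, ds = ds)
  }
  x <- sig(z, psf$gamma)
  y <- sig(z, -psf$gamma)
  list(sx = x$s, sy = y$s, dsx = x$ds, dsy = y$ds)
}

# 1D integrated-Gaussian factors over unit pixels and their derivatives.
# edges: 0..n; center position mu (px); width s (px).
axis_integrals <- function(n, mu, s) {
  hi <- (seq_len(n) - mu) / s
  lo <- (seq_len(n) - 1 - mu) / s
  E <- stats::pnorm(hi) - stats::pnorm(lo)
  phi_hi <- stats::dnorm(hi)
  phi_lo <- stats::dnorm(lo)
  dmu <- -(phi_hi - phi_lo) / s
  ds <- -(hi * phi_hi - lo * phi_lo) / s
  list(E = E, dmu = dmu, ds = ds)
}

#' Expected fractional photon count per ROI pixel
#'
#' Integrates the (possibly elliptical) Gaussian over each unit pixel of the
#' ROI via differences of the normal CDF along each axis. The map sums to at
#' most 1; for a PSF well inside the ROI it sums to 1 up to numerical
#' precision.
#'
#' @param psf a `psf_model`.
#' @param x,y emitter position within the ROI, in nm from the ROI origin
#'   (pixel width = `psf$pixel_size` nm).
#' @param z axial position (nm); ignored for 2D models.
#' @param roi_shape `c(rows, cols)` of the ROI.
#' @return matrix `rows x cols` of expected photon fractions.
#' @export
psf_pixel_integrals <- function(psf, x, y, z = 0, roi_shape) {
  stopifnot(inherits(psf, "psf_model"))
  roi_shape <- rep_len(as.integer(roi_shape), 2L)
  px <- psf$pixel_size
  if (x < 0 || x > roi_shape[2] * px || y < 0 || y > roi_shape[1] * px) {
    stop_arg("emitter position outside the ROI")
  }
  s <- psf_sigma(psf, z)
  if (s$sx <= 0 || s$sy <= 0) stop_arg("PSF width must be positive")
  ex <- axis_integrals(roi_shape[2], x / px, s$sx / px)
  ey <- axis_integrals(roi_shape[1], y / px, s$sy / px)
  outer(ey$E, ex$E)
}

# Model expectation and analytic parameter derivatives for theta =
# (x, y[, z], N, bg); x, y, z in nm, ROI-origin frame. Returns mu (without
# any variance shift) and a list of derivative matrices.
psf_model_derivs <- function(psf, theta, roi_shape) {
  roi_shape <- rep_len(as.integer(roi_shape), 2L)
  px <- psf$pixel_size
  z <- theta$z %||% 0
  s <- psf_sigma(psf, z)
  ex <- axis_integrals(roi_shape[2], theta$x / px, s$sx / px)
  ey <- axis_integrals(roi_shape[1], theta$y / px, s$sy / px)
  E <- outer(ey$E, ex$E)
  mu <- theta$N * E + theta$bg
  d <- list(
    x = theta$N * outer(ey$E, ex$dmu) / px,
    y = theta$N * outer(ey$dmu, ex$E) / px
  )
  if (psf$kind == "astigmatic3d") {
    # dE/dz = dE/dsx * dsx/dz + dE/dsy * dsy/dz, widths handled in px inside
    # axis_integrals, hence the 1/px on the chain rule.
    d$z <- theta$N * (outer(ey$E, ex$ds) * (s$dsx / px) +
                        outer(ey$ds, ex$E) * (s$dsy / px))
  }
  d$N <- E
  d$bg <- matrix(1, roi_shape[1], roi_shape[2])
  list(mu = mu, derivs = d, E = E)
}

#' Cramer-Rao lower bound for localization parameters
#'
#' Fisher information for the per-pixel-variance-aware Poisson model
#' `I_ij = sum_k (dmu_i dmu_j) / (mu_k + v_k)`, where `mu_k` is the expected
#' photoelectron count (`N * E_k + bg`) and `v_k` the Gaussian
#' (read + thermal) noise variance expressed in photoelectron units. The
#' CRLB is the diagonal of the inverse; its square root is the best
#' achievable precision of any unbiased estimator.
#'
#' @param psf a `psf_model`.
#' @param theta named list `x`, `y`, (`z`,) `N`, `bg`; positions in nm from
#'   the ROI origin, `N` expected photons, `bg` photons/pixel.
#' @param v per-pixel Gaussian variance in photoelectron units (scalar or
#'   matrix); 0 for an ideal camera.
#' @param roi_shape `c(rows, cols)`.
#' @return named vector of variance lower bounds (nm^2 for positions,
#'   photons^2 for `N`, `bg`).
#' @export
crlb <- function(psf, theta, v = 0, roi_shape) {
  md <- psf_model_derivs(psf, theta, roi_shape)
  denom <- md$mu + v
  if (any(denom <= 0)) stop_arg("model + variance must be positive on all pixels")
  nms <- names(md$derivs)
  np <- length(nms)
  I <- matrix(0, np, np, dimnames = list(nms, nms))
  for (i in seq_len(np)) {
    for (j in i:np) {
      I[i, j] <- I[j, i] <- sum(md$derivs[[i]] * md$derivs[[j]] / denom)
    }
  }
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) / max(ev) < 1e-14) {
    worst <- nms[which.min(diag(I))]
    stop_arg("singular Fisher matrix (degenerate parameter '%s')", worst)
  }
  ivar <- diag(solve(I))
  names(ivar) <- nms
  ivar
}
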