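# Controlled fitting scenarios on a homogeneous camera; uniform maps make
# the expected photoelectron model exact.

noise_free_roi <- function(maps, psf, th, shape = c(7, 7)) {
  E <- psf_pixel_integrals(psf, th$x, th$y, th$z %||% 0, shape)
  maps$offset + maps$photon_response * (th$N * E + th$bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("noise-free data is recovered to sub-millipixel accuracy", {
  gt <- uniform_camera(c(7L, 7L), dc = 20, rn = 1.5, gain = 2)
  for (psf in list(psf_gauss2d(), psf_astigmatic3d())) {
    maps <- derive_maps(gt, 0.05)
    th <- list(x = 3.31 * 98, y = 3.72 * 98, z = 60, N = 4000, bg = 12)
    roi <- noise_free_roi(maps, psf, th)
    fit <- mle_fit(roi, maps, psf)
    e <- fit$estimates
    expect_true(e$converged)
    expect_lt(abs(e$x - th$x), 1e-3 * 98)
    expect_lt(abs(e$y - th$y), 1e-3 * 98)
    if (psf$kind == "astigmatic3d") expect_lt(abs(e$z - th$z), 1)
    expect_lt(abs(e$photons - th$N) / th$N, 1e-3)
    expect_lt(abs(e$bg - th$bg), 0.05)
  }
})

test_that("the optimum dominates a dense grid search of the likelihood", {
  gt <- uniform_camera(c(7L, 7L), dc = 30, rn = 1.5, gain = 2)
  psf <- psf_gauss2d()
  maps <- derive_maps(gt, 0.05)
  px <- psf$pixel_size
  for (seed in 1:3) {
    em <- emitter_truth(3.5 * px, 3.5 * px, 0, photons = 800, bg = 8)
    sim <- simulate_smlm_frames(gt, psf, em, 0.05, 1, roi_size = 7L,
                                seed = seed)
    fit <- mle_fit(sim$rois[, , 1], maps, psf)

    # dense 4-parameter grid evaluation of the same objective
    off <- maps$offset[1, 1]; pr <- maps$photon_response[1, 1]
    v <- maps$variance[1, 1] / pr^2
    d <- (sim$rois[, , 1] - off) / pr + v
    ll_at <- function(x, y, N, bg) {
      m <- pmax(N * psf_pixel_integrals(psf, x, y, 0, c(7, 7)) + bg + v,
                1e-6)
      sum(d * log(m) - m)
    }
    grid <- expand.grid(x = seq(2.6, 4.4, length.out = 13) * px,
                        y = seq(2.6, 4.4, length.out = 13) * px,
                        N = seq(500, 1200, length.out = 11),
                        bg = seq(4, 14, length.out = 6))
    ll_grid <- mapply(ll_at, grid$x, grid$y, grid$N, grid$bg)
    expect_gte(fit$estimates$loglik, max(ll_grid) - 1e-9)
  }
})

test_that("with zero auxiliary variance the fit is standard Poisson MLE", {
  psf <- psf_gauss2d()
  px <- psf$pixel_size
  # ideal camera: offset 0, unit photon response, no read/thermal noise
  maps <- structure(list(exposure_time = 0.05,
                         offset = matrix(0, 9, 9),
                         variance = matrix(0, 9, 9),
                         photon_response = matrix(1, 9, 9)),
                    class = "derived_maps")
  set.seed(77)
  E <- psf_pixel_integrals(psf, 4.3 * px, 4.6 * px, 0, c(9, 9))
  roi <- matrix(rpois(81, 1500 * E + 10), 9, 9)
  fit <- mle_fit(roi, maps, psf)

  # independent route: generic optimizer on the plain Poisson likelihood
  nll <- function(p) {
    m <- pmax(p[3] * psf_pixel_integrals(psf, p[1], p[2], 0, c(9, 9)) +
                p[4], 1e-6)
    -sum(roi * log(m) - m)
  }
  o <- optim(c(4.5 * px, 4.5 * px, sum(roi) - 81 * 10, 10), nll,
             method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  expect_lt(abs(fit$estimates$x - o$par[1]), 1e-2)
  expect_lt(abs(fit$estimates$y - o$par[2]), 1e-2)
  expect_lt(abs(fit$estimates$photons - o$par[3]) / o$par[3], 1e-3)
  expect_gte(fit$estimates$loglik, -o$value - 1e-6)
})

test_that("mirroring the ROI and maps mirrors the fitted x", {
  gt <- make_synthetic_camera(c(9, 9), 0, seed = 55)
  psf <- psf_gauss2d()
  px <- psf$pixel_size
  maps <- derive_maps(gt, 0.05)
  em <- emitter_truth(4.12 * px, 4.5 * px, 0, photons = 2000, bg = 15)
  sim <- simulate_smlm_frames(gt, psf, em, 0.05, 1, roi_size = 9L, seed = 6)
  fit <- mle_fit(sim$rois[, , 1], maps, psf, rows = sim$rows,
                 cols = sim$cols)

  mirror <- function(m) m[, ncol(m):1]
  maps_m <- maps
  for (f in c("offset", "variance", "photon_response")) {
    maps_m[[f]] <- mirror(maps_m[[f]][sim$rows, sim$cols])
  }
  fit_m <- mle_fit(mirror(sim$rois[, , 1]), maps_m, psf)
  expect_lt(abs(fit_m$estimates$x - (9 * px - fit$estimates$x)), 1e-6 * px)
  expect_equal(fit_m$estimates$loglik, fit$estimates$loglik,
               tolerance = 1e-9)
})

test_that("no estimator beats the CRLB beyond sampling noise", {
  gt <- uniform_camera(c(9L, 9L), dc = 20, rn = 1.5, gain = 2)
  psf <- psf_astigmatic3d()
  px <- psf$pixel_size
  maps <- derive_maps(gt, 0.05)
  n <- 400
  em <- emitter_truth(4.5 * px, 4.5 * px, 0, photons = 3000, bg = 15)
  sim <- simulate_smlm_frames(gt, psf, em, 0.05, n, roi_size = 9L, seed = 8)
  fit <- mle_fit(sim$rois, maps, psf, rows = sim$rows, cols = sim$cols)
  e <- fit$estimates[fit$estimates$converged, ]
  th <- list(x = sim$truth$x, y = sim$truth$y, z = 0, N = 3000, bg = 15)
  v <- maps$variance[sim$rows, sim$cols] /
    maps$photon_response[sim$rows, sim$cols]^2
  cr <- crlb(psf, th, v, c(9, 9))
  floor_frac <- 1 - 3 / sqrt(2 * n)
  expect_gte(sd(e$x), sqrt(cr[["x"]]) * floor_frac)
  expect_gte(sd(e$y), sqrt(cr[["y"]]) * floor_frac)
  expect_gte(sd(e$z), sqrt(cr[["z"]]) * floor_frac)
  expect_gte(sd(e$photons), sqrt(cr[["N"]]) * floor_frac)
})

test_that("iteration starvation is flagged, not thrown", {
  gt <- uniform_camera(c(7L, 7L), dc = 20)
  psf <- psf_gauss2d()
  maps <- derive_maps(gt, 0.05)
  em <- emitter_truth(3.5 * 98, 3.5 * 98, 0, photons = 1000, bg = 10)
  sim <- simulate_smlm_frames(gt, psf, em, 0.05, 1, roi_size = 7L, seed = 2)
  fit <- mle_fit(sim$rois[, , 1], maps, psf, max_iter = 1L)
  expect_false(fit$estimates$converged)
  expect_true(all(is.finite(unlist(fit$estimates[1:5]))))
})
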