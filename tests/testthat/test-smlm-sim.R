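test_that("an ideal camera reduces the simulation to pure Poisson imaging", {
  gt <- uniform_camera(c(11L, 11L), baseline = 0, dc = 0, rn = 0, gain = 1)
  gt$flatfield[] <- 1
  psf <- psf_gauss2d()
  px <- psf$pixel_size
  em <- emitter_truth(5.5 * px, 5.5 * px, 0, photons = 900, bg = 5)
  n <- 3000
  sim <- simulate_smlm_frames(gt, psf, em, t = 0.05, n_repeats = n,
                              roi_size = 11L, seed = 13)
  mu <- 900 * psf_pixel_integrals(psf, sim$truth$x, sim$truth$y, 0,
                                  c(11, 11)) + 5
  m <- apply(sim$rois, c(1, 2), mean)
  se <- sqrt(mu / n)
  expect_true(all(abs(m - mu) < 4 * se + 1e-9))
})

test_that("photon sampling modes behave as configured", {
  gt <- uniform_camera(c(11L, 11L))
  psf <- psf_gauss2d()
  em <- emitter_truth(5.5 * 98, 5.5 * 98, 0, photons = 1000, bg = 5)
  fixed <- simulate_smlm_frames(gt, psf, em, 0.05, 5, "fixed",
                                roi_size = 11L, seed = 1)
  expect_true(all(fixed$photons == 1000))

  sampler <- function(n) seq(100, 100 * n, by = 100)
  dist <- simulate_smlm_frames(gt, psf, em, 0.05, 5, "distribution",
                               photon_sampler = sampler, roi_size = 11L,
                               seed = 1)
  expect_identical(dist$photons, c(100, 200, 300, 400, 500))
  expect_error(simulate_smlm_frames(gt, psf, em, 0.05, 5, "distribution",
                                    roi_size = 11L), "photon_sampler")

  # ROI must stay on the detector
  edge <- emitter_truth(0.5 * 98, 5.5 * 98, 0, photons = 1000, bg = 5)
  expect_error(simulate_smlm_frames(gt, psf, edge, 0.05, 1, roi_size = 11L),
               "outside")
})

test_that("modality presets carry the documented photon parameterizations", {
  expect_equal(modality_preset("palm")$photons, 3420)
  expect_equal(modality_preset("storm")$photons, 9000)
  expect_equal(modality_preset("paint")$photons, 35100)
  expect_equal(modality_preset("palm", "industry")$photons, 1900)
  expect_equal(modality_preset("storm", "industry")$photons, 5000)
  expect_equal(modality_preset("paint", "industry")$photons, 19500)
  expect_equal(modality_preset("paint")$exposure_time, 0.5)
  expect_equal(modality_preset("palm")$exposure_time, 0.05)
})

test_that("bias experiments record one entry per grid position and fitter", {
  gt <- uniform_camera(c(24L, 24L))
  psf <- psf_gauss2d()
  pre <- list(photons = 800, exposure_time = 0.05, bg = 5)
  grid <- as.matrix(expand.grid(row = 11:12, col = 11:12))
  rep <- bias_rmse_experiment(gt, psf, pre, grid, n_repeats = 40, seed = 3)
  expect_identical(nrow(rep), 8L) # 4 positions x 2 fitters
  expect_setequal(unique(rep$fitter), c("corrected", "uncorrected"))
  expect_true(all(rep$rmse_x^2 >= rep$bias_x^2 - 1e-9))
  expect_true(all(is.infinite(rep$dist_hot))) # no hot pixels on this camera
})

test_that("a homogeneous camera needs no correction", {
  gt <- uniform_camera(c(24L, 24L), dc = 50, rn = 2, gain = 2)
  psf <- psf_gauss2d()
  pre <- list(photons = 2000, exposure_time = 0.1, bg = 10)
  grid <- as.matrix(expand.grid(row = 11:13, col = 11:13))
  rep <- bias_rmse_experiment(gt, psf, pre, grid, n_repeats = 300, seed = 9)
  co <- rep[rep$fitter == "corrected", ]
  un <- rep[rep$fitter == "uncorrected", ]
  # same data, identical maps after averaging: results statistically equal
  expect_lt(max(abs(co$bias_x - un$bias_x)), 1)
  expect_lt(max(abs(co$rmse_x / un$rmse_x - 1)), 0.05)
})

test_that("lateral bias flips sign on opposite sides of a hot pixel", {
  gt <- industry_fixture_camera(seed = 1)
  h <- central_hot_pixel(gt)
  psf <- psf_gauss2d()
  pre <- modality_preset("storm", "industry")
  grid <- rbind(c(h[1], h[2] - 1), c(h[1], h[2] + 1))
  rep <- bias_rmse_experiment(gt, psf, pre, grid, n_repeats = 300,
                              fitters = "uncorrected", seed = 4)
  expect_gt(rep$bias_x[1], 5)   # pulled toward the hot pixel (+x)
  expect_lt(rep$bias_x[2], -5)  # and from the other side (-x)
})
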