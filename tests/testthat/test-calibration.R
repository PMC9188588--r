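test_that("full calibration recovers the simulator's parameter maps", {
  gt <- make_synthetic_camera(c(32, 32), 0.01, seed = 21)
  tt <- c(0.001, 0.005, 0.02, 0.1, 0.5)
  cal <- calibrate_camera(stats_from_sim(gt, tt, n = 2000, seed = 100))

  expect_lt(sqrt(mean((cal$baseline - gt$baseline)^2)), 0.5)
  expect_lt(abs(cal$median_gain - median(gt$gain)) / median(gt$gain), 0.02)
  dc_true <- gt$gain * gt$dark_current
  expect_lt(median(abs(cal$dark_current_adu - dc_true) / dc_true), 0.05)
  rn2_true <- gt$gain^2 * gt$read_noise^2
  # quantization adds ~1/12 ADU^2 to the true intercept
  expect_lt(median(abs(cal$read_noise_sq_adu - rn2_true - 1 / 12)) /
              median(rn2_true), 0.1)

  # electron-domain views obey the stated unit conversions
  expect_equal(cal$diagnostics$dark_current_e_median,
               median(cal$dark_current_adu) / cal$median_gain)

  # Poisson self-consistency: thermal noise^2 slope equals gain * dark
  # current slope, estimated from two independent fits
  ratio <- median(cal$thermal_noise_sq_adu) /
    (cal$median_gain * median(cal$dark_current_adu))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("omitting the bright frame leaves a unit flatfield", {
  gt <- uniform_camera(c(8L, 8L))
  cal <- calibrate_camera(stats_from_sim(gt, c(0.001, 0.05, 0.2), 300,
                                         seed = 5))
  expect_true(all(cal$flatfield == 1))
  dm <- derive_maps(cal, 0.05)
  expect_true(all(dm$photon_response == cal$median_gain))
})

test_that("derived maps obey their defining identities", {
  gt <- make_synthetic_camera(c(16, 16), 0.01, seed = 3)
  cal <- calibrate_camera(stats_from_sim(gt, c(0.001, 0.02, 0.1, 0.4), 500,
                                         seed = 9))
  d0 <- derive_maps(cal, 0)
  expect_equal(d0$offset, cal$baseline)
  expect_equal(d0$variance, pmax(cal$read_noise_sq_adu, 0))

  # predict() is the modelling-idiom spelling of the same operation
  expect_equal(predict(cal, exposure_time = 0.1),
               derive_maps(cal, 0.1))

  # offsets grow monotonically with t wherever fitted dark current >= 0
  d1 <- derive_maps(cal, 0.05); d2 <- derive_maps(cal, 0.3)
  pos <- cal$dark_current_adu >= 0
  expect_true(all((d2$offset - d1$offset)[pos] >= 0))
  expect_error(derive_maps(cal, -0.1), ">= 0")
})

test_that("mean thermal offset at 10 ms equals dark current times time", {
  # camera built so mean gain * dark current = 56 ADU/s: the offset map at
  # 10 ms then exceeds the baseline by 0.56 counts on average
  gt <- uniform_camera(c(16L, 16L), dc = 28, gain = 2)
  dm <- derive_maps(gt, 0.01)
  expect_equal(mean(dm$offset - gt$baseline), 0.56, tolerance = 1e-6)
  expect_equal(thermal_offset_check(gt, 0.01, n_frames = Inf), 0.56,
               tolerance = 1e-6)
})

test_that("flatfield estimation separates sensitivity from illumination", {
  gt <- uniform_camera(c(32L, 32L), dc = 10)
  offset <- derive_maps(gt, 0.01)$offset
  photons <- 2000

  # uniform light, uniform sensitivity: flatfield is exactly 1
  bright <- offset + gt$gain * gt$flatfield * photons
  ff <- flatfield_from_bright(bright, offset)
  expect_lt(max(abs(ff - 1)), 1e-9)

  # a 10% more sensitive pixel shows up at its own position
  gt2 <- gt
  gt2$flatfield[16, 16] <- 1.10
  bright2 <- offset + gt$gain * gt2$flatfield * photons
  ff2 <- flatfield_from_bright(bright2, offset)
  expect_equal(ff2[16, 16], 1.10, tolerance = 0.005)

  # a smooth 2x illumination gradient is absorbed by the smoothing, not
  # mistaken for sensitivity structure (away from the image border)
  ramp <- matrix(rep(seq(1, 2, length.out = 32), each = 32), 32, 32)
  bright3 <- offset + gt$gain * gt$flatfield * photons * ramp
  ff3 <- flatfield_from_bright(bright3, offset)
  inner <- ff3[9:24, 9:24]
  expect_lt(max(abs(inner - 1)), 0.02)
  expect_lt(max(abs(ff3 - 1)), 0.15)

  expect_error(flatfield_from_bright(offset + 1, offset), "too dim")
  sat <- matrix(65535, 32, 32)
  expect_error(flatfield_from_bright(sat, offset), "saturated")
})

test_that("traditional light-level calibration carries the thermal offset", {
  gt <- make_synthetic_camera(c(16, 16), 0.01, seed = 31)
  t_light <- 0.01
  levels <- c(0, 300, 800, 2000)
  ls <- lapply(seq_along(levels), function(i) {
    simulate_light_stats(gt, levels[i], t_light, 3000, seed = 40 + i)
  })
  trad <- traditional_light_calibration(ls, levels)

  # offset exceeds the true baseline by the mean thermal signal at t_light
  excess <- mean(trad$offset - gt$baseline)
  expected <- mean(gt$gain * gt$dark_current) * t_light
  expect_lt(abs(excess - expected), 0.03)

  # gain agrees with the simulator truth
  expect_lt(abs(trad$median_gain - median(gt$gain)) / median(gt$gain), 0.02)

  expect_error(traditional_light_calibration(ls[1:2], levels[1:2]),
               "3 distinct")
  expect_error(traditional_light_calibration(ls[2:4], levels[2:4]),
               "darkness")
})

test_that("repeated calibrations of one camera agree within estimator noise", {
  gt <- make_synthetic_camera(c(16, 16), 0.01, seed = 8)
  tt <- c(0.001, 0.02, 0.1, 0.4)
  c1 <- calibrate_camera(stats_from_sim(gt, tt, 1500, seed = 1))
  c2 <- calibrate_camera(stats_from_sim(gt, tt, 1500, seed = 5000))
  expect_lt(abs(median(c1$baseline) - median(c2$baseline)), 0.05)
  expect_lt(abs(c1$median_gain - c2$median_gain) / c2$median_gain, 0.02)
})
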