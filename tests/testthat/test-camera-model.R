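test_that("synthetic camera construction honors its contracts", {
  gt <- make_synthetic_camera(c(100, 100), hot_pixel_fraction = 0.01,
                              seed = 42)
  expect_s3_class(gt, "camera_ground_truth")
  expect_identical(nrow(gt$hot_pixels), 100L)
  # flagged coordinates really are the extreme dark-current pixels
  expect_true(all(gt$dark_current[gt$hot_pixels] >=
                    10 * median(gt$dark_current)))

  gt2 <- make_synthetic_camera(c(100, 100), hot_pixel_fraction = 0.01,
                               seed = 42)
  expect_identical(gt, gt2)

  cold <- make_synthetic_camera(c(64, 64), hot_pixel_fraction = 0, seed = 7)
  expect_lt(max(cold$dark_current) / median(cold$dark_current), 10)
  expect_identical(nrow(cold$hot_pixels), 0L)

  expect_error(make_synthetic_camera(c(0, 10)), "shape")
  expect_error(make_synthetic_camera(c(8, 8), hot_pixel_fraction = 1),
               "hot_pixel_fraction")
})

test_that("dark-frame sample moments match the model's closed form", {
  gt <- uniform_camera(c(1L, 1L), baseline = 100, dc = 50, rn = 1, gain = 2)
  n <- 1e5
  fr <- simulate_dark_frames(gt, t = 0.5, n_frames = n, seed = 9)
  x <- as.vector(fr)
  # expected: mean 100 + 2*50*0.5 = 150; var 4*(1 + 25) = 104 (plus ~1/12
  # quantization)
  se_mean <- sqrt(104 / n)
  se_var <- 104 * sqrt(2 / n)
  expect_lt(abs(mean(x) - 150), 3 * se_mean)
  expect_lt(abs(var(x) - (104 + 1 / 12)), 3 * se_var)
})

test_that("with no noise sources every frame equals the rounded baseline", {
  gt <- uniform_camera(c(4L, 4L), baseline = 100.4, dc = 5, rn = 0)
  fr <- simulate_dark_frames(gt, t = 0, n_frames = 5, seed = 1)
  expect_true(all(fr == round(100.4)))
  expect_error(simulate_dark_frames(gt, t = -1), "non-negative")
})

test_that("quantized output respects the saturation ceiling", {
  gt <- uniform_camera(c(4L, 4L), baseline = 100, dc = 10, rn = 1, gain = 2,
                       bit_depth = 12L)
  fr <- simulate_bright_frames(gt, photons_per_pixel = 1e4, n_frames = 3,
                               seed = 2)
  expect_lte(max(fr), 2^12 - 1)
  expect_true(any(fr == 2^12 - 1)) # flux chosen far past saturation
})

test_that("bright frames reduce to dark frames at zero photons", {
  gt <- uniform_camera(c(8L, 8L))
  a <- simulate_bright_frames(gt, 0, t = 0.05, n_frames = 10, seed = 3)
  b <- simulate_dark_frames(gt, t = 0.05, n_frames = 10, seed = 3)
  expect_identical(a, b)
})

test_that("a more sensitive pixel collects proportionally more light", {
  gt <- uniform_camera(c(8L, 8L), dc = 0, rn = 1)
  gt$flatfield[3, 3] <- 1.1
  n <- 4000
  photons <- 1000
  fr <- simulate_bright_frames(gt, photons, t = 0, n_frames = n, seed = 4)
  m <- apply(fr, c(1, 2), mean)
  signal <- (m - gt$baseline) / gt$gain
  others <- signal[-3, -3]
  ratio <- signal[3, 3] / mean(others)
  se <- 1.1 / sqrt(photons * n) * 3 # generous 3-SE band on the ratio
  expect_lt(abs(ratio - 1.1), 3 * se)
  expect_error(simulate_bright_frames(gt, -5), ">= 0")
})

test_that("exposure series bookkeeping and schedule equivalence hold", {
  gt <- uniform_camera(c(6L, 6L), dc = 100)
  tt <- c(0.001, 0.1, 0.5)
  nested <- simulate_dark_series(gt, tt, n_per_time = 120, seed = 5,
                                 schedule = "nested")
  blocked <- simulate_dark_series(gt, tt, n_per_time = 120, seed = 5,
                                  schedule = "blocked")
  expect_identical(length(nested$frames), 3L)
  expect_true(all(vapply(nested$frames, function(f) dim(f)[3], 0) == 120))
  expect_identical(nested$schedule, "nested")

  # pooled means agree between schedules within sampling error
  for (i in seq_along(tt)) {
    mn <- mean(nested$frames[[i]])
    mb <- mean(blocked$frames[[i]])
    se <- sd(as.vector(blocked$frames[[i]])) / sqrt(120 * 36)
    expect_lt(abs(mn - mb), 3 * sqrt(2) * se)
  }

  # positive dark current makes the pooled mean strictly increasing in t
  means <- vapply(nested$frames, mean, 0)
  expect_true(all(diff(means) > 0))

  expect_error(simulate_dark_series(gt, c(0.1, 0.2), 10), "3 distinct")

  # identical seeds reproduce the series exactly
  again <- simulate_dark_series(gt, tt, n_per_time = 120, seed = 5,
                                schedule = "nested")
  expect_identical(nested, again)
})

test_that("variance-to-mean ratio recovers the gain for pure Poisson pixels", {
  # the relation the whole photon-free method rests on
  gt <- uniform_camera(c(8L, 8L), dc = 100, rn = 0, gain = 2.3)
  st <- simulate_dark_stats(gt, t = 0.2, n_frames = 5000, seed = 6)
  ratio <- st$variance / (st$mean - gt$baseline)
  # per-pixel relative sd of the variance is sqrt(2/n); median over 64 px
  expect_lt(abs(median(ratio) - 2.3) / 2.3, 3 * sqrt(2 / 5000))
})

test_that("pooled mean and variance are linear in exposure time", {
  gt <- uniform_camera(c(8L, 8L), dc = 50)
  tt <- c(0.001, 0.02, 0.1, 0.25, 0.5)
  st <- stats_from_sim(gt, tt, n = 5000, seed = 70)
  pooled_mean <- apply(st$mean, 3, mean)
  pooled_var <- apply(st$variance, 3, mean)
  r2 <- function(y) summary(lm(y ~ tt))$r.squared
  expect_gt(r2(pooled_mean), 0.999)
  expect_gt(r2(pooled_var), 0.999)
})
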