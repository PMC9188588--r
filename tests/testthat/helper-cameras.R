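# Shared camera constructors for tests.

# Perfectly homogeneous camera: every pixel identical, no hot pixels.
uniform_camera <- function(shape = c(16L, 16L), baseline = 100, dc = 25,
                           rn = 1.5, gain = 2, seed = 1L, bit_depth = 16L) {
  make_synthetic_camera(
    shape, hot_pixel_fraction = 0,
    parameter_ranges = list(
      baseline_mean = baseline, baseline_amplitude = 0, baseline_jitter = 0,
      dark_current_median = dc, dark_current_sdlog = 1e-12,
      read_noise_range = c(rn, rn), gain_mean = gain, gain_sd = 0,
      flatfield_sd = 1e-12, bit_depth = bit_depth),
    seed = seed)
}

# pixel_stats built from simulated streaming moments.
stats_from_sim <- function(gt, times, n, seed = 1L) {
  mom <- lapply(seq_along(times), function(i) {
    simulate_dark_stats(gt, times[i], n, seed = seed + i)
  })
  pixel_stats_from_moments(times, lapply(mom, `[[`, "mean"),
                           lapply(mom, `[[`, "variance"), n)
}
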