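test_that("resampling preserves already-uniform series and validates span", {
  bs <- uniform_series(0.3, 2, duration_s = 60, dt = 0.1)
  rs <- resample_beat_series(bs, fs_resample = 10)
  # grid coincides with the original sampling: values preserved (mean aside)
  expect_lt(max(abs(rs$values - (bs$values - mean(bs$values)))), 1e-9)
  expect_error(resample_beat_series(uniform_series(0.3, 1, duration_s = 10)),
               "30 s")
  expect_error(resample_beat_series(bs, fs_resample = 2), ">= 4")
})

test_that("interpolated RMS of a beat-sampled sinusoid matches closed form", {
  # sinusoid sampled at irregular beat-like times, ~6 Hz
  set.seed(2)
  tt <- cumsum(runif(1100, 0.14, 0.18))
  bs <- beat_series(tt, 3 * sin(2 * pi * 0.3 * tt), "sbp", "mmHg")
  rs <- resample_beat_series(bs, 10)
  expect_rel_error(sqrt(mean(rs$values^2)), 3 / sqrt(2), 0.01)
})

test_that("wavelet band power is calibrated to A^2/2 and band-confined", {
  bands <- default_bands()
  bs <- uniform_series(0.3, 2, duration_s = 180)
  rs <- resample_beat_series(bs)
  lf <- wavelet_band_power(rs, bands$lf)
  expect_rel_error(lf$mean_power, 2, 0.05)
  # periodogram oracle equivalence
  oracle <- periodogram_band_power(rs$values, rs$fs, 0.15, 0.6)
  expect_rel_error(lf$mean_power, oracle, 0.05)

  # a 1.2 Hz tone leaks < 1% of its HF power into the LF band
  hs <- uniform_series(1.2, 1.5, duration_s = 180, kind = "hr", units = "bpm")
  rh <- resample_beat_series(hs)
  hf <- wavelet_band_power(rh, bands$hf)
  lf_leak <- wavelet_band_power(rh, bands$lf)
  expect_lt(lf_leak$mean_power / hf$mean_power, 0.01)
  expect_rel_error(hf$mean_power, 1.5^2 / 2, 0.05)

  # zero signal -> zero power
  zs <- resample_beat_series(uniform_series(0.3, 0, duration_s = 120))
  expect_lt(wavelet_band_power(zs, bands$lf)$mean_power, 1e-20)

  expect_error(wavelet_band_power(rs, band_definition("X", 1, 20)), "Nyquist")
})

test_that("CWT band power agrees with the periodogram on two-tone signals", {
  bands <- default_bands()
  tt <- seq(0, 180, by = 0.1)
  two <- beat_series(tt, 2 * sin(2 * pi * 0.3 * tt) +
                          1.5 * sin(2 * pi * 1.2 * tt), "mix")
  rs <- resample_beat_series(two)
  lf <- wavelet_band_power(rs, bands$lf)$mean_power
  hf <- wavelet_band_power(rs, bands$hf)$mean_power
  # band additivity: each band sees only its own tone
  expect_rel_error(lf, 2, 0.05)
  expect_rel_error(hf, 1.5^2 / 2, 0.05)
  expect_rel_error(lf, periodogram_band_power(rs$values, rs$fs, 0.15, 0.6),
                   0.05)
  expect_rel_error(hf, periodogram_band_power(rs$values, rs$fs, 0.6, 2.0),
                   0.05)
})

test_that("scale invariance: power scales as c^2, LF/HF invariant", {
  bands <- default_bands()
  set.seed(9)
  tt <- cumsum(runif(900, 0.14, 0.18))
  vals <- 2 * sin(2 * pi * 0.3 * tt) + rnorm(length(tt), 0, 0.3)
  for (c_scale in c(0.5, 3)) {
    b1 <- beat_series(tt, vals, "sbp")
    b2 <- beat_series(tt, c_scale * vals, "sbp")
    p1 <- wavelet_band_power(resample_beat_series(b1), bands$lf)$mean_power
    p2 <- wavelet_band_power(resample_beat_series(b2), bands$lf)$mean_power
    expect_rel_error(p2, c_scale^2 * p1, 1e-6)
  }
})

test_that("lf_hf_ratio contracts: values, scale invariance, undefined flag", {
  expect_equal(lf_hf_ratio(2, 2), 1)
  expect_equal(lf_hf_ratio(0, 5), 0)
  for (h in c(0.01, 1, 250))
    expect_equal(lf_hf_ratio(0.54 * h, h), 0.54)
  r <- lf_hf_ratio(1, 0)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_error(lf_hf_ratio(-1, 2))
})

test_that("analyze_window recovers a calibrated LF/HF target", {
  p <- make_group_params("CTL")
  b <- simulate_baseline_recording(p, 180, 250, seed = 11)
  ai <- analyze_window(b$truth$sbp, b$truth$hr)
  expect_rel_error(ai$lf_hf_ratio, 1.14, 0.10)
  expect_false(ai$ratio_undefined)

  # symmetry: equal amplitudes at both carriers give a ratio near 1
  p2 <- p; p2$lf_amp_mmHg <- 1.5; p2$hf_amp_bpm <- 1.5; p2$noise[] <- 0
  b2 <- simulate_baseline_recording(p2, 180, 250, seed = 1)
  ai2 <- analyze_window(b2$truth$sbp, b2$truth$hr)
  expect_rel_error(ai2$lf_hf_ratio, 1, 0.05)

  # no HF modulation and no noise -> undefined ratio flag
  p3 <- p; p3$hf_amp_bpm <- 0; p3$noise[] <- 0
  b3 <- simulate_baseline_recording(p3, 180, 250, seed = 1)
  ai3 <- analyze_window(b3$truth$sbp, b3$truth$hr)
  expect_true(ai3$ratio_undefined)
  expect_true(is.na(ai3$lf_hf_ratio))

  expect_error(analyze_window(b$truth$sbp, b$truth$hr, start_s = 100,
                              window_s = 180), "not covered")
})

test_that("mean LF/HF across seeded recordings stays within 10% of target", {
  p <- make_group_params("CTL")
  ratios <- vapply(1:8, function(s) {
    b <- simulate_baseline_recording(p, 180, 250, seed = 20 + s)
    analyze_window(b$truth$sbp, b$truth$hr)$lf_hf_ratio
  }, 0)
  expect_rel_error(mean(ratios), 1.14, 0.10)
})
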