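test_that("group parameter defaults match the published group means", {
  ctl <- make_group_params("CTL")
  expect_equal(ctl$hr_bpm, 379)
  expect_equal(ctl$sbp_mmHg, 150)
  expect_equal(ctl$dbp_mmHg, 111)
  expect_equal(ctl$collagen_fraction_pct, 59.9)
  expect_equal(ctl$brg_bpm_per_mmHg, 0.28)
  expect_equal(ctl$lf_hf_target, 1.14)
  expect_equal(ctl$hf_power_bpm2, 1.13)
  expect_equal(unname(ctl$catecholamines["noradrenaline"]), 76.20)

  d16 <- make_group_params("DOX16")
  expect_equal(d16$brg_bpm_per_mmHg, 0.49)
  expect_equal(d16$collagen_fraction_pct, 65.8)
  expect_equal(d16$rf_stim_cpm - d16$rf_basal_cpm, 15.4)

  # LF/HF calibration identity: lf_amp^2 / hf_amp^2 = target ratio
  for (g in c("CTL", "DOX8", "DOX16", "DOX20")) {
    p <- make_group_params(g)
    expect_equal(p$lf_amp_mmHg^2 / p$hf_amp_bpm^2, p$lf_hf_target)
  }
  expect_error(make_group_params("DOX5"), "CTL, DOX8, DOX16, DOX20")
})

test_that("baseline generator is deterministic and validates arguments", {
  p <- make_group_params("CTL")
  b1 <- simulate_baseline_recording(p, 180, 250, seed = 42)
  b2 <- simulate_baseline_recording(p, 180, 250, seed = 42)
  expect_identical(b1$truth$beat_times, b2$truth$beat_times)
  expect_identical(b1$channels$ecg$samples, b2$channels$ecg$samples)
  b3 <- simulate_baseline_recording(p, 180, 250, seed = 43)
  expect_false(identical(b1$channels$ecg$samples, b3$channels$ecg$samples))
  expect_error(simulate_baseline_recording(p, 60, 250), "180")
  expect_error(simulate_baseline_recording(p, 180, 50), "100 Hz")
})

test_that("zero modulation and zero noise give a constant RR at hr_bpm", {
  p <- make_group_params("CTL")
  p$hf_amp_bpm <- 0; p$lf_amp_mmHg <- 0; p$noise[] <- 0
  b <- simulate_baseline_recording(p, 180, 500, seed = 1)
  rr <- diff(b$truth$beat_times)
  expect_lt(diff(range(rr)), 1e-6)
  expect_equal(mean(60 / rr), 379, tolerance = 1e-6)
  peaks <- detect_r_peaks(b$channels$ecg)
  hr <- rr_and_hr(peaks)$hr
  expect_equal(mean(hr$values), 379, tolerance = 0.01)
})

test_that("generated SBP series carries the programmed LF band power", {
  p <- make_group_params("CTL")
  p$noise[] <- 0
  b <- simulate_baseline_recording(p, 180, 250, seed = 5)
  rs <- resample_beat_series(b$truth$sbp)
  # analytic sinusoid power oracle via periodogram band integral
  oracle <- periodogram_band_power(rs$values, rs$fs, 0.15, 0.6)
  expect_rel_error(oracle, p$lf_amp_mmHg^2 / 2, 0.03)
  # band confinement: out-of-band power < 1% of in-band at zero noise
  total <- periodogram_band_power(rs$values, rs$fs, 0, rs$fs / 2)
  inb <- periodogram_band_power(rs$values, rs$fs,
                                p$lf_freq_Hz - 0.05, p$lf_freq_Hz + 0.05)
  expect_lt((total - inb) / inb, 0.01)
})

test_that("phenylephrine generator couples HR to the ramp as programmed", {
  p <- make_group_params("CTL")
  p$noise[] <- 0; p$hf_amp_bpm <- 0; p$lf_amp_mmHg <- 0
  b <- simulate_phenylephrine_response(p, ramp_mmHg = 40, ramp_s = 60,
                                       sampling_rate = 250, seed = 1)
  tr <- b$truth
  pre <- tr$hr$values[tr$hr$times < 60]
  post <- tr$hr$values[tr$hr$times > 120 & tr$hr$times < 145]
  expect_equal(mean(pre), 379, tolerance = 1e-6)
  expect_equal(mean(pre) - mean(post), 0.28 * 40, tolerance = 0.05)
  # brg = 0 leaves HR flat through the ramp
  p0 <- p; p0$brg_bpm_per_mmHg <- 0
  b0 <- simulate_phenylephrine_response(p0, 40, 60, sampling_rate = 250,
                                        seed = 1)
  expect_lt(diff(range(b0$truth$hr$values)), 1e-6)
  expect_error(simulate_phenylephrine_response(p, ramp_mmHg = -3), "positive")
})

test_that("lobeline generator steps the tracheal frequency at the event", {
  p <- make_group_params("DOX8")
  expect_equal(p$rf_stim_cpm - p$rf_basal_cpm, 12.5)
  b <- simulate_lobeline_response(p, sampling_rate = 250, seed = 2)
  expect_equal(event_time(b, "lobeline"), 60)
  rf <- respiratory_frequency(b$channels$tracheal, window_s = 15)
  basal <- rf$values[rf$times < 60]
  stim <- rf$values[rf$times > 60]
  expect_equal(mean(basal), 60, tolerance = 0.5)
  expect_equal(mean(stim), 72.5, tolerance = 0.5)
})

test_that("cohort draws respect the design and are seed-stable", {
  des <- group_design(groups = c("CTL", "DOX16"))
  expect_equal(des$arms$CTL$n, 6)
  expect_equal(des$arms$DOX16$n, 8)
  co <- simulate_cohort(des, seed = 3, recordings = FALSE, image_px = 0)
  expect_length(co$subjects, 14)
  co2 <- simulate_cohort(des, seed = 3, recordings = FALSE, image_px = 0)
  expect_identical(vapply(co$subjects, function(s) s$params$hr_bpm, 0),
                   vapply(co2$subjects, function(s) s$params$hr_bpm, 0))
  co3 <- simulate_cohort(des, seed = 4, recordings = FALSE, image_px = 0)
  expect_false(identical(vapply(co$subjects, function(s) s$params$hr_bpm, 0),
                         vapply(co3$subjects, function(s) s$params$hr_bpm, 0)))
  # catecholamine table: one row per subject and analyte
  expect_equal(nrow(co$catecholamines), 14 * 3)
  expect_true(all(co$catecholamines$value >= 0))
})

test_that("zero-SD design yields identical subjects at the group means", {
  des <- group_design(groups = "CTL", sd_scale = 0)
  co <- simulate_cohort(des, seed = 1, recordings = FALSE, image_px = 0)
  hrs <- vapply(co$subjects, function(s) s$params$hr_bpm, 0)
  expect_true(all(hrs == 379))
  sbps <- vapply(co$subjects, function(s) s$params$sbp_mmHg, 0)
  expect_true(all(sbps == 150))
})

test_that("cohort group means track design means (sampling oracle)", {
  # 2-SEM band check on variables without meaningful truncation; the
  # between-subject SD is SEM * sqrt(n), so the mean of n draws has SD
  # equal to the printed SEM
  des <- group_design(groups = c("CTL", "DOX16"))
  reps <- 10
  hr_means <- sbp_means <- numeric(reps)
  for (s in seq_len(reps)) {
    # cohort seeds spaced beyond the cohort size: subject seeds are
    # cohort seed + index, so nearby cohort seeds share subject streams
    co <- simulate_cohort(des, seed = 1000 * s, recordings = FALSE,
                          image_px = 0)
    hr_means[s] <- mean(vapply(co$subjects[1:6],
                               function(x) x$params$hr_bpm, 0))
    sbp_means[s] <- mean(vapply(co$subjects[7:14],
                                function(x) x$params$sbp_mmHg, 0))
  }
  # each cohort mean ~ N(design mean, SEM); the average of `reps`
  # independent cohort means stays within 3 SEM / sqrt(reps)
  expect_lt(abs(mean(hr_means) - 379), 3 * 22 / sqrt(reps))
  expect_lt(abs(mean(sbp_means) - 107), 3 * 9.2 / sqrt(reps))
  # and individual cohort means respect a 3-SEM envelope
  expect_true(all(abs(hr_means - 379) < 3 * 22))
  expect_true(all(abs(sbp_means - 107) < 3 * 9.2))
})

test_that("histology generator hits the requested pixel fraction exactly", {
  h <- simulate_histology_image(0, 128, 128, seed = 1)
  expect_equal(sum(h$collagen_mask), 0)
  h100 <- simulate_histology_image(100, 128, 128, seed = 1)
  expect_equal(sum(h100$collagen_mask), sum(h100$tissue_mask))
  h40 <- simulate_histology_image(40, 128, 128, seed = 1)
  expect_equal(sum(h40$collagen_mask),
               floor(0.40 * sum(h40$tissue_mask)))
  expect_true(all(h40$tissue_mask[h40$collagen_mask]))
  expect_error(simulate_histology_image(101, 64, 64), "\\[0, 100\\]")
  expect_error(simulate_histology_image(-1, 64, 64), "\\[0, 100\\]")
})
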