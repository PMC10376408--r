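ramp_series <- function(slope_bpm_per_mmHg, ramp_mmHg = 40, ramp_s = 60,
                        hr0 = 379, bp0 = 129, dt = 0.16) {
  tt <- seq(0, 60 + ramp_s + 20, by = dt)
  dbp <- ramp_mmHg * pmin(pmax((tt - 60) / ramp_s, 0), 1)
  list(mbp = beat_series(tt, bp0 + dbp, "mbp", "mmHg"),
       hr = beat_series(tt, hr0 - slope_bpm_per_mmHg * dbp, "hr", "bpm"),
       win = reflex_window(60, "phenylephrine"))
}

test_that("noise-free ramps return the programmed slope to < 1%", {
  for (slope in c(0.1, 0.28, 0.49, 1.2)) {
    r <- ramp_series(slope)
    br <- baroreflex_gain(r$mbp, r$hr, r$win)
    expect_rel_error(br$gain, slope, 0.01)
    expect_lt(br$delta_hr, 0)  # bradycardic direction retained
  }
  # 10 mmHg ramp boundary case from the contract
  r10 <- ramp_series(0.28, ramp_mmHg = 10)
  expect_rel_error(baroreflex_gain(r10$mbp, r10$hr, r10$win)$gain, 0.28, 0.01)
})

test_that("gain is invariant to constant baseline offsets", {
  r <- ramp_series(0.35)
  br0 <- baroreflex_gain(r$mbp, r$hr, r$win)
  mbp2 <- beat_series(r$mbp$times, r$mbp$values + 25, "mbp", "mmHg")
  hr2 <- beat_series(r$hr$times, r$hr$values - 80, "hr", "bpm")
  br1 <- baroreflex_gain(mbp2, hr2, r$win)
  expect_equal(br1$gain, br0$gain, tolerance = 1e-12)
  expect_equal(br1$delta_bp, br0$delta_bp, tolerance = 1e-12)
})

test_that("flat HR gives zero gain; flat BP is rejected as failed provocation", {
  r <- ramp_series(0)
  expect_equal(baroreflex_gain(r$mbp, r$hr, r$win)$gain, 0)
  flat <- ramp_series(0.28, ramp_mmHg = 1e-9)
  expect_error(baroreflex_gain(flat$mbp, flat$hr, flat$win),
               "failed provocation")
  expect_error(baroreflex_gain(r$mbp, r$hr,
                               reflex_window(60, "lobeline")),
               "phenylephrine")
})

test_that("simulated phenylephrine trials recover the gain within 5%", {
  for (g in c("CTL", "DOX16")) {
    p <- make_group_params(g)
    b <- simulate_phenylephrine_response(p, 40, 60, sampling_rate = 500,
                                         seed = 4)
    pk <- detect_r_peaks(b$channels$ecg)
    s <- rr_and_hr(pk)
    pb <- extract_bp_beats(b$channels$abp, pk)
    win <- reflex_window_from_bundle(b, "phenylephrine")
    br <- baroreflex_gain(pressure_series(pb, "mbp"), s$hr, win)
    expect_rel_error(br$gain, p$brg_bpm_per_mmHg, 0.05)
  }
})

test_that("regression-slope estimator agrees on noise-free ramps", {
  r <- ramp_series(0.28)
  reg <- baroreflex_gain_regression(r$mbp, r$hr, r$win)
  expect_rel_error(reg$gain, 0.28, 0.01)
  expect_lt(reg$slope, 0)
})

test_that("chemoreflex delta: construction, zero case, window validation", {
  tt <- seq(7.5, 120, by = 15)
  rf <- beat_series(tt, ifelse(tt < 60, 60, 72.5), "rf", "cpm")
  win <- reflex_window(60, "lobeline", baseline_s = 45, response_s = 60)
  ch <- chemoreflex_delta(rf, win)
  expect_equal(ch$delta_rf, 12.5)
  expect_equal(ch$rf_basal, 60)
  expect_equal(ch$rf_stim, 72.5)

  rf0 <- beat_series(tt, rep(60, length(tt)), "rf", "cpm")
  expect_equal(chemoreflex_delta(rf0, win)$delta_rf, 0)

  narrow <- reflex_window(60, "lobeline", baseline_s = 45, response_s = 60)
  rf_sparse <- beat_series(c(10, 30, 50), c(60, 60, 60), "rf", "cpm")
  expect_error(chemoreflex_delta(rf_sparse, narrow), "shorter than")
  expect_error(chemoreflex_delta(rf, reflex_window(60, "phenylephrine")),
               "lobeline")
})

test_that("noisy lobeline trials recover the programmed step within 1 cpm", {
  p <- make_group_params("DOX8")
  for (s in 1:3) {
    b <- simulate_lobeline_response(p, sampling_rate = 250, seed = s)
    rf <- respiratory_frequency(b$channels$tracheal, window_s = 15)
    win <- reflex_window_from_bundle(b, "lobeline", baseline_s = 45,
                                     response_s = 60)
    ch <- chemoreflex_delta(rf, win)
    expect_lt(abs(ch$delta_rf - 12.5), 1)
  }
})

test_that("reflex window invariants", {
  w <- reflex_window(60, "phenylephrine")
  expect_lte(w$baseline["end_s"], w$injection_time_s)
  expect_equal(unname(w$response["start_s"]), w$injection_time_s)
  expect_error(reflex_window(10, "lobeline", baseline_s = 30), "before")
  expect_error(reflex_window(60, "lobeline", response_s = 0), "positive")
})
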