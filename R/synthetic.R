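# Synthetic rat cardiovascular recordings with known ground truth.
#
# The generator is phenomenological: it reproduces the statistical structure
# the analysis assumes (a mean heart rate with a respiratory-frequency HF
# oscillation, per-beat systolic levels with a low-frequency oscillation, a
# linear pressor ramp with baroreflex-coupled HR fall, a respiratory-rate
# step, clustered red collagen on a yellow myocardium) -- not the underlying
# physiology. Every programmed quantity is retained as ground truth on the
# returned bundle so downstream estimators have an exact recovery oracle.

# Normalized arterial pulse shape over one beat, u in [0, 1):
# w(u) = u^1.5 (1-u)^3.5 scaled to max 1. Zero at both ends (diastole),
# early peak (u* = 0.3, fast systolic upstroke). Its time-average (~0.455)
# fixes the mBP/sBP/dBP relation of the generated waveforms.
pulse_shape <- function(u) {
  w <- u^1.5 * (1 - u)^3.5
  ustar <- 0.3
  w / (ustar^1.5 * (1 - ustar)^3.5)
}
PULSE_SHAPE_MEAN <- 0.4553  # \int_0^1 w(u) du, Beta(2.5, 4.5) integral

# printed group-level values (means and SEMs) for the four study arms
group_value_table <- function() {
  g <- c("CTL", "DOX8", "DOX16", "DOX20")
  tab <- list(
    n            = c(6, 8, 8, 8),
    hr_bpm       = c(379, 360, 290, 242),    # DOX8 not printed; see vignette
    hr_sem       = c(22, 22, 26, 25),
    sbp_mmHg     = c(150, 136, 107, 104.9),
    sbp_sem      = c(5.3, 4.7, 9.2, 7.2),
    dbp_mmHg     = c(111, 97.5, 84, 73),     # DOX8 interpolated; see vignette
    dbp_sem      = c(3.9, 4.7, 9.2, 6.6),
    brg          = c(0.28, 0.37, 0.49, 0.24),
    brg_sem      = c(0.02, 0.04, 0.06, 0.3),
    delta_rf_cpm = c(8.4, 12.5, 15.4, 7.2),
    delta_rf_sem = c(1.1, 1, 1.9, 0.8),
    lf_hf        = c(1.14, 0.54, 0.69, 0.21),
    lf_hf_sem    = c(0.19, 0.16, 0.39, 0.12),
    hf_power     = c(1.13, 1.13, 1.13, 22.23),  # only CTL/DOX20 printed
    collagen_pct = c(59.9, 55.04, 65.8, 65.7),
    collagen_sem = c(0.95, 0.25, 2.36, 1.88),
    adrenaline   = c(19.77, 28.91, 28.16, 22.20),
    adrenaline_sem   = c(2.044, 6.827, 5.302, 11.33),
    noradrenaline    = c(76.20, 73.96, 111.2, 125.6),
    noradrenaline_sem = c(11.89, 14.24, 24.75, 62.80),
    dopamine     = c(669.5, 615.2, 707.0, 623.4),
    dopamine_sem = c(145.2, 144.8, 145.9, 287.6))
  lapply(tab, function(v) stats::setNames(v, g))
}

#' Default subject parameters for one study arm
#'
#' Returns the generator parameter set calibrated to the published group
#' means of the four arms (saline control and three cumulative doxorubicin
#' doses). LF/HF calibration follows the band-power identity for sinusoidal
#' oscillations: a systolic oscillation of amplitude `lf_amp` carries LF
#' power `lf_amp^2/2` (mmHg^2) and a heart-rate oscillation of amplitude
#' `hf_amp` carries HF power `hf_amp^2/2` (bpm^2), so amplitudes are set
#' from the target HF power and LF/HF ratio.
#'
#' @param group one of `"CTL"`, `"DOX8"`, `"DOX16"`, `"DOX20"`.
#' @return An object of class `"subject_params"`; a list with heart rate
#'   (bpm), systolic/diastolic pressure (mmHg), LF and HF oscillation
#'   amplitude and carrier frequency, baroreflex slope (bpm/mmHg), basal and
#'   stimulated respiratory frequency (cycles/min), collagen fraction (%),
#'   urinary catecholamine levels (ng/mL) and per-channel noise SDs.
#' @export
make_group_params <- function(group) {
  if (length(group) != 1L || !group %in% VALID_GROUPS)
    stop("unknown group '", paste(group, collapse = ","),
         "'; valid groups: ", paste(VALID_GROUPS, collapse = ", "))
  tab <- group_value_table()
  v <- function(name) unname(tab[[name]][group])
  hf_power <- v("hf_power")
  lf_hf <- v("lf_hf")
  structure(list(
    group = group,
    hr_bpm = v("hr_bpm"),
    sbp_mmHg = v("sbp_mmHg"),
    dbp_mmHg = v("dbp_mmHg"),
    lf_freq_Hz = 0.3,                 # mid LF band (0.15-0.6 Hz)
    hf_freq_Hz = 1.2,                 # mid HF band (0.6-2.0 Hz)
    lf_hf_target = lf_hf,
    hf_power_bpm2 = hf_power,
    hf_amp_bpm = sqrt(2 * hf_power),
    lf_amp_mmHg = sqrt(2 * lf_hf * hf_power),
    brg_bpm_per_mmHg = v("brg"),
    rf_basal_cpm = 60,
    rf_stim_cpm = 60 + v("delta_rf_cpm"),
    collagen_fraction_pct = v("collagen_pct"),
    catecholamines = c(adrenaline = v("adrenaline"),
                       noradrenaline = v("noradrenaline"),
                       dopamine = v("dopamine")),
    noise = c(sbp_beat = 0.5,   # mmHg, per-beat systolic jitter
              hr_beat = 0.2,    # bpm, per-beat rate jitter
              ecg = 0.02,       # mV additive on the 1 mV R wave
              abp = 0.5,        # mmHg additive on the pressure waveform
              tracheal = 0.05)  # cmH2O additive
  ), class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(paste0("<subject_params %s> HR %g bpm, sBP/dBP %g/%g mmHg, ",
                     "BRG %g bpm/mmHg, dRF %g cpm, LF/HF %g, collagen %g%%\n"),
              x$group, x$hr_bpm, x$sbp_mmHg, x$dbp_mmHg, x$brg_bpm_per_mmHg,
              x$rf_stim_cpm - x$rf_basal_cpm, x$lf_hf_target,
              x$collagen_fraction_pct))
  invisible(x)
}

#' Cohort design: group sizes and between-subject spread
#'
#' Between-subject SDs are reconstructed from the published standard errors
#' as `SEM * sqrt(n)` (the study reports mean +/- SEM).
#'
#' @param groups which arms to include (default all four).
#' @param sd_scale multiplier on every between-subject SD; `0` gives a
#'   cohort of identical subjects at the group means.
#' @return An object of class `"group_design"`.
#' @export
group_design <- function(groups = VALID_GROUPS, sd_scale = 1) {
  stopifnot(all(groups %in% VALID_GROUPS), sd_scale >= 0)
  tab <- group_value_table()
  arms <- lapply(groups, function(g) {
    n <- unname(tab$n[g])
    sdv <- function(sem_name) {
      s <- unname(tab[[sem_name]][g]) * sqrt(n) * sd_scale
      if (is.na(s) || s < 0) { warning("non-positive SD for ", sem_name,
                                       " in ", g, "; using 0"); s <- 0 }
      s
    }
    list(group = g, n = n, params = make_group_params(g),
         sd = c(hr_bpm = sdv("hr_sem"), sbp_mmHg = sdv("sbp_sem"),
                dbp_mmHg = sdv("dbp_sem"), brg = sdv("brg_sem"),
                delta_rf = sdv("delta_rf_sem"), lf_hf = sdv("lf_hf_sem"),
                collagen = sdv("collagen_sem"),
                adrenaline = sdv("adrenaline_sem"),
                noradrenaline = sdv("noradrenaline_sem"),
                dopamine = sdv("dopamine_sem")))
  })
  names(arms) <- groups
  structure(list(arms = arms), class = "group_design")
}

# instantaneous heart rate (bpm) and its running beat count used to place
# beat times; rate = hr + hf_amp sin(2 pi f t) + optional extra (e.g. the
# baroreflex-coupled fall during a pressor ramp), evaluated on a fine grid
beat_times_from_rate <- function(rate_fun, duration_s, grid_hz = 1000) {
  tg <- seq(0, duration_s, by = 1 / grid_hz)
  r <- rate_fun(tg)
  if (any(r <= 0)) stop("instantaneous heart rate must stay positive")
  # cumulative beat count by trapezoidal integration of rate/60
  cn <- c(0, cumsum((r[-1] + r[-length(r)]) / 2) / grid_hz / 60)
  k <- seq(0, floor(cn[length(cn)]))
  stats::approx(cn, tg, xout = k, ties = "ordered")$y
}

gaussian_r_wave_train <- function(beat_times, duration_s, fs, amp = 1,
                                  sigma_s = 0.008) {
  n <- floor(duration_s * fs) + 1L
  x <- numeric(n)
  half <- ceiling(4 * sigma_s * fs)
  for (bt in beat_times) {
    ic <- round(bt * fs) + 1
    idx <- max(1, ic - half):min(n, ic + half)
    tt <- (idx - 1) / fs
    x[idx] <- x[idx] + amp * exp(-(tt - bt)^2 / (2 * sigma_s^2))
  }
  x
}

# arterial pressure waveform from per-beat systolic levels and a (possibly
# time-varying) diastolic level; dbp_at is a function of time
abp_from_beats <- function(beat_times, sbp_levels, dbp_at, duration_s, fs) {
  n <- floor(duration_s * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  p <- rep(dbp_at(tt[1]), n)
  nb <- length(beat_times)
  idx_start <- pmin(pmax(findInterval(beat_times, tt), 1L), n)
  for (i in seq_len(nb - 1L)) {
    i0 <- idx_start[i]; i1 <- idx_start[i + 1L] - 1L
    if (i1 < i0) next
    seg <- i0:i1
    u <- (tt[seg] - beat_times[i]) / (beat_times[i + 1L] - beat_times[i])
    d <- dbp_at(tt[seg])
    p[seg] <- d + (sbp_levels[i] - d) * pulse_shape(pmin(pmax(u, 0), 1))
  }
  if (idx_start[nb] <= n) p[idx_start[nb]:n] <- dbp_at(tt[idx_start[nb]:n])
  if (idx_start[1] > 1) p[1:(idx_start[1] - 1L)] <- dbp_at(tt[1:(idx_start[1] - 1L)])
  p
}

build_truth <- function(beat_times, hr_vals, sbp_vals, dbp_at_beats, params) {
  nb <- length(beat_times)
  mbp_vals <- dbp_at_beats + PULSE_SHAPE_MEAN * (sbp_vals - dbp_at_beats)
  list(beat_times = beat_times,
       hr = beat_series(beat_times, hr_vals, "hr", "bpm"),
       sbp = beat_series(beat_times[-nb], sbp_vals[-nb], "sbp", "mmHg"),
       mbp = beat_series(beat_times[-nb], mbp_vals[-nb], "mbp", "mmHg"),
       dbp = beat_series(beat_times[-nb], dbp_at_beats[-nb], "dbp", "mmHg"),
       params = params)
}

#' Simulate a baseline (unstimulated) recording
#'
#' ECG is a Gaussian R-wave train whose instantaneous rate is
#' `hr_bpm + hf_amp sin(2 pi hf_freq t)` plus per-beat noise; arterial
#' pressure is a train of beat-synchronous pulse waves whose per-beat
#' systolic level is `sbp_mmHg + lf_amp sin(2 pi lf_freq t)` plus noise,
#' with diastolic level `dbp_mmHg`; tracheal pressure is a sinusoid at the
#' basal respiratory frequency. Ground-truth beat times and per-beat values
#' are attached as `$truth`.
#'
#' @param params a [make_group_params()] object (fields may be overridden).
#' @param duration_s recording length, >= 180 s (one analysis window).
#' @param sampling_rate waveform sampling rate in Hz, >= 100.
#' @param seed integer seed; fixed seed gives an identical bundle.
#' @return A [recording_bundle()] with channels `ecg`, `abp`, `tracheal`.
#' @export
simulate_baseline_recording <- function(params, duration_s = 180,
                                        sampling_rate = 500, seed = 1) {
  stopifnot(inherits(params, "subject_params"))
  if (duration_s < 180)
    stop("duration_s must cover at least one 180-s analysis window")
  if (sampling_rate < 100) stop("sampling_rate must be >= 100 Hz")
  if (duration_s < 10 / params$lf_freq_Hz)
    warning("recording shorter than 10 LF cycles; spectral resolution poor")
  set.seed(as.integer(seed))
  p <- params
  rate_fun <- function(t) p$hr_bpm + p$hf_amp_bpm * sin(2 * pi * p$hf_freq_Hz * t)
  bt <- beat_times_from_rate(rate_fun, duration_s)
  nb <- length(bt)
  hr_vals <- rate_fun(bt) + stats::rnorm(nb, 0, p$noise["hr_beat"])
  sbp_vals <- p$sbp_mmHg + p$lf_amp_mmHg * sin(2 * pi * p$lf_freq_Hz * bt) +
    stats::rnorm(nb, 0, p$noise["sbp_beat"])
  n <- floor(duration_s * sampling_rate) + 1L
  tt <- (seq_len(n) - 1) / sampling_rate
  ecg <- gaussian_r_wave_train(bt, duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["ecg"])
  abp <- abp_from_beats(bt, sbp_vals, function(t) rep(p$dbp_mmHg, length(t)),
                        duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["abp"])
  trach <- sin(2 * pi * p$rf_basal_cpm / 60 * tt) +
    stats::rnorm(n, 0, p$noise["tracheal"])
  ch <- list(
    ecg = waveform(ecg, sampling_rate, "ecg", "mV"),
    abp = waveform(abp, sampling_rate, "abp", "mmHg"),
    tracheal = waveform(trach, sampling_rate, "tracheal", "cmH2O"))
  recording_bundle(ch, NULL, subject_id = "synthetic", group = p$group,
                   truth = build_truth(bt, hr_vals, sbp_vals,
                                       rep(p$dbp_mmHg, nb), p))
}

#' Simulate a phenylephrine pressor-ramp trial
#'
#' After a 60-s baseline, blood pressure rises linearly by `ramp_mmHg` over
#' `ramp_s` seconds and then holds; heart rate falls by
#' `brg_bpm_per_mmHg` times the instantaneous pressure rise (the programmed
#' baroreflex coupling). The injection event is labelled `"phenylephrine"`.
#'
#' @inheritParams simulate_baseline_recording
#' @param ramp_mmHg total pressure rise, > 0.
#' @param ramp_s ramp duration in seconds.
#' @return A [recording_bundle()] with the injection event and ground truth.
#' @export
simulate_phenylephrine_response <- function(params, ramp_mmHg = 40,
                                            ramp_s = 60, sampling_rate = 500,
                                            seed = 1) {
  stopifnot(inherits(params, "subject_params"))
  if (ramp_mmHg <= 0) stop("ramp_mmHg must be positive")
  if (ramp_s <= 0) stop("ramp_s must be positive")
  set.seed(as.integer(seed))
  p <- params
  t_inj <- 60
  duration_s <- t_inj + ramp_s + 30
  # the ramp shifts the whole pressure wave uniformly, so the programmed
  # HR coupling (brg x instantaneous delta-BP) is recoverable from the
  # measured mean-pressure delta -- the generator's ground-truth contract
  dbp_rise_frac <- 1
  dBP <- function(t) ramp_mmHg * pmin(pmax((t - t_inj) / ramp_s, 0), 1)
  rate_fun <- function(t)
    p$hr_bpm + p$hf_amp_bpm * sin(2 * pi * p$hf_freq_Hz * t) -
      p$brg_bpm_per_mmHg * dBP(t)
  bt <- beat_times_from_rate(rate_fun, duration_s)
  nb <- length(bt)
  hr_vals <- rate_fun(bt) + stats::rnorm(nb, 0, p$noise["hr_beat"])
  sbp_vals <- p$sbp_mmHg + dBP(bt) +
    p$lf_amp_mmHg * sin(2 * pi * p$lf_freq_Hz * bt) +
    stats::rnorm(nb, 0, p$noise["sbp_beat"])
  dbp_at <- function(t) p$dbp_mmHg + dbp_rise_frac * dBP(t)
  n <- floor(duration_s * sampling_rate) + 1L
  tt <- (seq_len(n) - 1) / sampling_rate
  ecg <- gaussian_r_wave_train(bt, duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["ecg"])
  abp <- abp_from_beats(bt, sbp_vals, dbp_at, duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["abp"])
  trach <- sin(2 * pi * p$rf_basal_cpm / 60 * tt) +
    stats::rnorm(n, 0, p$noise["tracheal"])
  ch <- list(
    ecg = waveform(ecg, sampling_rate, "ecg", "mV"),
    abp = waveform(abp, sampling_rate, "abp", "mmHg"),
    tracheal = waveform(trach, sampling_rate, "tracheal", "cmH2O"))
  ev <- data.frame(label = "phenylephrine", time = t_inj)
  recording_bundle(ch, ev, subject_id = "synthetic", group = p$group,
                   truth = c(build_truth(bt, hr_vals, sbp_vals, dbp_at(bt), p),
                             list(ramp_mmHg = ramp_mmHg, ramp_s = ramp_s,
                                  injection_time = t_inj)))
}

#' Simulate a lobeline chemoreflex trial
#'
#' The tracheal-pressure frequency steps (phase-continuously) from the basal
#' to the stimulated respiratory rate at the injection event, labelled
#' `"lobeline"`. Both segments last 60 s.
#'
#' @inheritParams simulate_baseline_recording
#' @return A [recording_bundle()] with channels `tracheal`, `ecg`, `abp`.
#' @export
simulate_lobeline_response <- function(params, sampling_rate = 500, seed = 1) {
  stopifnot(inherits(params, "subject_params"))
  if (params$rf_stim_cpm < 0) stop("rf_stim_cpm must be >= 0")
  set.seed(as.integer(seed))
  p <- params
  t_inj <- 60
  duration_s <- 120
  n <- floor(duration_s * sampling_rate) + 1L
  tt <- (seq_len(n) - 1) / sampling_rate
  f0 <- p$rf_basal_cpm / 60; f1 <- p$rf_stim_cpm / 60
  phase <- 2 * pi * ifelse(tt <= t_inj, f0 * tt,
                           f0 * t_inj + f1 * (tt - t_inj))
  trach <- sin(phase) + stats::rnorm(n, 0, p$noise["tracheal"])
  rate_fun <- function(t) p$hr_bpm + p$hf_amp_bpm * sin(2 * pi * p$hf_freq_Hz * t)
  bt <- beat_times_from_rate(rate_fun, duration_s)
  nb <- length(bt)
  hr_vals <- rate_fun(bt) + stats::rnorm(nb, 0, p$noise["hr_beat"])
  sbp_vals <- p$sbp_mmHg + p$lf_amp_mmHg * sin(2 * pi * p$lf_freq_Hz * bt) +
    stats::rnorm(nb, 0, p$noise["sbp_beat"])
  ecg <- gaussian_r_wave_train(bt, duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["ecg"])
  abp <- abp_from_beats(bt, sbp_vals, function(t) rep(p$dbp_mmHg, length(t)),
                        duration_s, sampling_rate) +
    stats::rnorm(n, 0, p$noise["abp"])
  ch <- list(
    ecg = waveform(ecg, sampling_rate, "ecg", "mV"),
    abp = waveform(abp, sampling_rate, "abp", "mmHg"),
    tracheal = waveform(trach, sampling_rate, "tracheal", "cmH2O"))
  ev <- data.frame(label = "lobeline", time = t_inj)
  recording_bundle(ch, ev, subject_id = "synthetic", group = p$group,
                   truth = c(build_truth(bt, hr_vals, sbp_vals,
                                         rep(p$dbp_mmHg, nb), p),
                             list(rf_basal_cpm = p$rf_basal_cpm,
                                  rf_stim_cpm = p$rf_stim_cpm,
                                  injection_time = t_inj)))
}

# vectorized HSV -> RGB without string round-trips
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# smooth random field via FFT low-pass of white noise; used to cluster the
# collagen pixels into blob-like patches rather than salt-and-pepper
smooth_field <- function(height, width, cutoff_cycles = 8) {
  z <- matrix(stats::rnorm(height * width), height, width)
  fy <- c(0:(floor(height / 2)), -((ceiling(height / 2) - 1):1)) / height
  fx <- c(0:(floor(width / 2)), -((ceiling(width / 2) - 1):1)) / width
  fr2 <- outer(fy^2, fx^2, `+`)
  filt <- exp(-fr2 / (2 * (cutoff_cycles / max(height, width))^2))
  Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (height * width)
}

#' Simulate a picrosirius-red-stained section image
#'
#' A tissue blob (wavy ellipse) on a near-white background; within the
#' tissue, exactly `floor(fraction * tissue_px / 100)` pixels are drawn from
#' a red collagen-like colour distribution and the rest from a yellow
#' myocardium-like one. Collagen pixels are spatially clustered (threshold
#' of a smooth random field), emulating fibrotic patches.
#'
#' @param collagen_fraction_pct programmed collagen percentage in \[0, 100\].
#' @param width,height image size in pixels.
#' @param seed integer seed.
#' @return A list with `image` (height x width x 3 array in \[0, 1\]),
#'   `tissue_mask` and `collagen_mask` (logical matrices) and
#'   `fraction_pct` (the exact pixel fraction realized).
#' @export
simulate_histology_image <- function(collagen_fraction_pct, width = 512,
                                     height = 512, seed = 1) {
  if (!is.finite(collagen_fraction_pct) || collagen_fraction_pct < 0 ||
      collagen_fraction_pct > 100)
    stop("collagen_fraction_pct must lie in [0, 100]")
  set.seed(as.integer(seed))
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  cx <- width / 2; cy <- height / 2
  th <- atan2(yy - cy, xx - cx)
  rad <- sqrt(((xx - cx) / (0.42 * width))^2 + ((yy - cy) / (0.45 * height))^2)
  wob <- 1 + 0.07 * sin(5 * th + stats::runif(1, 0, 2 * pi)) +
    0.04 * sin(9 * th + stats::runif(1, 0, 2 * pi))
  tissue <- rad <= wob
  tissue_px <- sum(tissue)
  if (tissue_px == 0) stop("degenerate image geometry")
  m <- floor(collagen_fraction_pct * tissue_px / 100)
  collagen <- matrix(FALSE, height, width)
  if (m > 0) {
    fld <- smooth_field(height, width)
    vals <- fld[tissue]
    ord <- order(vals, decreasing = TRUE)
    idx <- which(tissue)[ord[seq_len(m)]]
    collagen[idx] <- TRUE
  }
  npx <- height * width
  h <- s <- v <- numeric(npx)
  bg <- !tissue
  nbg <- sum(bg)
  h[bg] <- stats::runif(nbg, 0.08, 0.14)
  s[bg] <- pmax(0, stats::rnorm(nbg, 0.03, 0.01))
  v[bg] <- pmin(1, stats::rnorm(nbg, 0.97, 0.01))
  myo <- tissue & !collagen
  nmy <- sum(myo)
  h[myo] <- stats::rnorm(nmy, 0.13, 0.012)          # yellow
  s[myo] <- pmin(1, pmax(0.3, stats::rnorm(nmy, 0.65, 0.05)))
  v[myo] <- pmin(0.9, pmax(0.4, stats::rnorm(nmy, 0.8, 0.04)))
  ncl <- sum(collagen)
  if (ncl) {
    h[collagen] <- (stats::rnorm(ncl, 0.985, 0.012)) %% 1   # red, hue wrap
    s[collagen] <- pmin(1, pmax(0.45, stats::rnorm(ncl, 0.8, 0.05)))
    v[collagen] <- pmin(0.8, pmax(0.3, stats::rnorm(ncl, 0.55, 0.05)))
  }
  rgb <- hsv_to_rgb(h, s, v)
  img <- array(0, dim = c(height, width, 3))
  img[, , 1] <- rgb$r; img[, , 2] <- rgb$g; img[, , 3] <- rgb$b
  list(image = img, tissue_mask = tissue, collagen_mask = collagen,
       fraction_pct = 100 * m / tissue_px)
}

truncated_draw <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (k in 1:100) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

#' Simulate a full cohort
#'
#' Draws per-subject parameters from each arm's distribution (normal with
#' SD = SEM * sqrt(n), truncated at physiological bounds), then generates
#' the requested raw data per subject. Subject seeds are
#' `seed + subject index` within the cohort, so any subject can be
#' regenerated in isolation.
#'
#' @param design a [group_design()].
#' @param seed integer cohort seed.
#' @param baseline_s baseline recording length per subject (s).
#' @param sampling_rate waveform sampling rate (Hz).
#' @param image_px histology image side length (pixels); 0 skips histology.
#' @param recordings logical; generate waveform bundles (baseline and both
#'   reflex trials)? If `FALSE` only parameters, histology and the
#'   catecholamine table are produced.
#' @return An object of class `"cohort"`: list with `subjects` (each holding
#'   `params`, `subject_id`, and when requested `baseline`, `phenylephrine`,
#'   `lobeline` bundles and `histology`) and `catecholamines` (long-format
#'   group table).
#' @export
simulate_cohort <- function(design, seed = 1, baseline_s = 180,
                            sampling_rate = 500, image_px = 256,
                            recordings = TRUE) {
  stopifnot(inherits(design, "group_design"))
  subjects <- list(); cat_rows <- list()
  sidx <- 0L
  for (arm in design$arms) {
    for (j in seq_len(arm$n)) {
      sidx <- sidx + 1L
      sseed <- as.integer(seed) + sidx
      set.seed(sseed)
      base <- arm$params
      p <- base
      p$hr_bpm <- truncated_draw(1, base$hr_bpm, arm$sd["hr_bpm"], lower = 50)
      p$sbp_mmHg <- truncated_draw(1, base$sbp_mmHg, arm$sd["sbp_mmHg"],
                                   lower = 40)
      p$dbp_mmHg <- min(truncated_draw(1, base$dbp_mmHg, arm$sd["dbp_mmHg"],
                                       lower = 20), p$sbp_mmHg - 10)
      p$brg_bpm_per_mmHg <- truncated_draw(1, base$brg_bpm_per_mmHg,
                                           arm$sd["brg"], lower = 0)
      drf <- truncated_draw(1, base$rf_stim_cpm - base$rf_basal_cpm,
                            arm$sd["delta_rf"], lower = -base$rf_basal_cpm)
      p$rf_stim_cpm <- base$rf_basal_cpm + drf
      p$lf_hf_target <- truncated_draw(1, base$lf_hf_target,
                                       arm$sd["lf_hf"], lower = 0.01)
      p$lf_amp_mmHg <- sqrt(2 * p$lf_hf_target * p$hf_power_bpm2)
      p$collagen_fraction_pct <- truncated_draw(
        1, base$collagen_fraction_pct, arm$sd["collagen"], 0, 100)
      p$catecholamines <- c(
        adrenaline = truncated_draw(1, base$catecholamines["adrenaline"],
                                    arm$sd["adrenaline"], lower = 0),
        noradrenaline = truncated_draw(1, base$catecholamines["noradrenaline"],
                                       arm$sd["noradrenaline"], lower = 0),
        dopamine = truncated_draw(1, base$catecholamines["dopamine"],
                                  arm$sd["dopamine"], lower = 0))
      id <- sprintf("%s_%02d", arm$group, j)
      subj <- list(subject_id = id, params = p, seed = sseed)
      if (recordings) {
        subj$baseline <- simulate_baseline_recording(
          p, duration_s = baseline_s, sampling_rate = sampling_rate,
          seed = sseed)
        subj$baseline$subject_id <- id
        subj$phenylephrine <- simulate_phenylephrine_response(
          p, sampling_rate = sampling_rate, seed = sseed + 10000L)
        subj$phenylephrine$subject_id <- id
        subj$lobeline <- simulate_lobeline_response(
          p, sampling_rate = sampling_rate, seed = sseed + 20000L)
        subj$lobeline$subject_id <- id
      }
      if (image_px > 0)
        subj$histology <- simulate_histology_image(
          p$collagen_fraction_pct, width = image_px, height = image_px,
          seed = sseed + 30000L)
      subjects[[id]] <- subj
      cat_rows[[id]] <- data.frame(
        subject = id, group = arm$group,
        variable = names(p$catecholamines),
        value = unname(p$catecholamines), units = "ng/mL")
    }
  }
  structure(list(subjects = subjects,
                 catecholamines = do.call(rbind, c(cat_rows,
                                                   make.row.names = FALSE))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  gl <- vapply(x$subjects, function(s) s$params$group, "")
  cat("<cohort>", length(x$subjects), "subjects:",
      paste(sprintf("%s n=%d", names(table(gl)), as.integer(table(gl))),
            collapse = ", "), "\n")
  invisible(x)
}
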