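# Beat detection and beat-indexed series extraction.

# zero-phase FFT band-pass; adequate for fixed-length offline records and
# avoids a filter-design dependency
fft_bandpass <- function(x, fs, f_lo, f_hi, transition = 1) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  xp <- c(x - mean(x), rep(0, nfft - n))
  f <- (seq_len(nfft) - 1) / nfft * fs
  f <- pmin(f, fs - f)  # two-sided
  ramp <- function(ff, edge) pmin(pmax((ff - edge) / transition + 0.5, 0), 1)
  mask <- ramp(f, f_lo) * (1 - ramp(f, f_hi))
  Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE))[seq_len(n)] / nfft
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R-peaks in an ECG waveform
#'
#' A Pan-Tompkins-style detector: band-pass (5-30 Hz), differentiate,
#' square, moving-window integrate (30 ms), threshold at a fraction of the
#' upper envelope, enforce the refractory period implied by `max_rate_bpm`,
#' and refine each detection to the raw-signal maximum within +/- 20 ms.
#'
#' @param ecg a [waveform()], duration >= 2 s.
#' @param min_rate_bpm,max_rate_bpm plausible heart-rate range; the
#'   refractory period is `60 / max_rate_bpm` seconds.
#' @param threshold_frac detection threshold as a fraction of the median of
#'   the top-percentile integrated energy (default 0.25).
#' @return Numeric vector of R-peak times in seconds (empty, with a
#'   warning, if nothing crosses threshold).
#' @export
detect_r_peaks <- function(ecg, min_rate_bpm = 120, max_rate_bpm = 600,
                           threshold_frac = 0.25) {
  stopifnot(inherits(ecg, "waveform"))
  fs <- ecg$sampling_rate
  if (waveform_duration(ecg) < 2) stop("ECG must be at least 2 s long")
  if (min_rate_bpm <= 0 || max_rate_bpm <= min_rate_bpm)
    stop("need 0 < min_rate_bpm < max_rate_bpm")
  x <- ecg$samples
  bp <- fft_bandpass(x, fs, 5, min(30, fs / 2 - 1))
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  w <- max(3L, round(0.030 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  top <- stats::quantile(integ, 0.99)
  if (top <= 0 || stats::sd(x) == 0) {
    warning("no QRS complexes detected (flat or featureless signal)")
    return(numeric())
  }
  thr <- threshold_frac * stats::median(integ[integ >= top])
  cand <- local_maxima(integ)
  cand <- cand[integ[cand] >= thr]
  if (!length(cand)) {
    warning("no QRS complexes detected above threshold")
    return(numeric())
  }
  refr <- round(60 / max_rate_bpm * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (integ[i] > integ[keep[length(keep)]]) {
      keep[length(keep)] <- i   # stronger peak inside refractory window wins
      last <- i
    }
  }
  # map back to the raw-signal maximum within +/- 20 ms
  half <- round(0.020 * fs)
  n <- length(x)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + half))
    lo + which.max(x[lo:hi]) - 1L
  }, 0L)
  peaks <- sort(unique(peaks))
  # a second refractory pass after refinement
  if (length(peaks) > 1L) {
    ok <- c(TRUE, diff(peaks) >= refr)
    peaks <- peaks[ok]
  }
  # sub-sample refinement: without it peak times are quantized to the
  # sample grid and the quantization noise inflates HF power of the derived
  # HR series. A near-Gaussian R wave is parabolic in log-amplitude, so fit
  # a least-squares quadratic to log|x| over +/- 3 samples and take the
  # vertex; fall back to the grid peak when the fit is not concave.
  half_fit <- max(2L, as.integer(round(0.006 * fs)))  # +/- 6 ms
  frac <- numeric(length(peaks))
  inner <- which(peaks > half_fit & peaks <= n - half_fit)
  if (length(inner)) {
    offs <- -half_fit:half_fit
    A <- cbind(1, offs, offs^2)
    pinv <- solve(crossprod(A), t(A))   # 3 x (2*half_fit+1)
    base <- stats::quantile(abs(x), 0.1) + 1e-12
    vals <- matrix(0, length(inner), length(offs))
    pk_amp <- x[peaks[inner]] - stats::median(x)
    for (k in seq_along(offs))
      vals[, k] <- log(pmax(x[peaks[inner] + offs[k]] - stats::median(x),
                            0.05 * pmax(pk_amp, base)))
    coef <- vals %*% t(pinv)
    a2 <- coef[, 3]; a1 <- coef[, 2]
    adj <- ifelse(a2 < 0, -a1 / (2 * a2), 0)
    lim <- half_fit / 2  # vertex may sit a few samples off the grid argmax
    frac[inner] <- pmin(pmax(adj, -lim), lim)
  }
  ecg$start_time + (peaks - 1 + frac) / fs
}

#' RR intervals and beat-to-beat heart rate from R-peak times
#'
#' `rr[i] = (t[i+1] - t[i]) * 1000` ms and `hr[i] = 60000 / rr[i]` bpm, both
#' timestamped at the later beat, so `hr * rr == 60000` exactly.
#'
#' @param peak_times strictly increasing R-peak times (seconds), length >= 2.
#' @return list with elements `rr` and `hr`, both [beat_series()].
#' @export
rr_and_hr <- function(peak_times) {
  if (length(peak_times) < 2L)
    stop("need at least 2 R-peaks to form RR intervals")
  if (any(diff(peak_times) <= 0)) stop("peak times must be strictly increasing")
  rr <- diff(peak_times) * 1000
  t_at <- peak_times[-1L]
  list(rr = beat_series(t_at, rr, "rr", "ms"),
       hr = beat_series(t_at, 60000 / rr, "hr", "bpm"))
}

#' Per-beat systolic, diastolic and mean pressure
#'
#' For each half-open beat window `[t_i, t_{i+1})`: systolic = maximum,
#' diastolic = minimum, mean = time-average of the pressure samples. The
#' final partial beat is dropped; windows with fewer than 3 samples are
#' skipped with a warning.
#'
#' @param abp arterial-pressure [waveform()].
#' @param beat_times R-peak (beat onset) times within the waveform span.
#' @return An object of class `"pressure_beats"`: data frame
#'   `(time, sbp, dbp, mbp)` with one row per complete beat.
#' @export
extract_bp_beats <- function(abp, beat_times) {
  stopifnot(inherits(abp, "waveform"))
  nb <- length(beat_times)
  if (nb < 2L) stop("need at least 2 beat times")
  tt <- waveform_times(abp)
  if (min(beat_times) < tt[1] - 1e-9 ||
      max(beat_times) > tt[length(tt)] + 1e-9)
    stop("beat times fall outside the waveform span")
  idx <- findInterval(tt, beat_times)      # 0 before first beat
  inside <- idx >= 1L & idx <= nb - 1L
  grp <- idx[inside]
  xs <- abp$samples[inside]
  cnt <- tabulate(grp, nbins = nb - 1L)
  small <- which(cnt > 0L & cnt < 3L)
  if (length(small))
    warning(length(small), " beat window(s) with < 3 samples skipped")
  ok <- cnt >= 3L
  sbp <- vapply(split(xs, grp), max, 0)
  dbp <- vapply(split(xs, grp), min, 0)
  mbp <- vapply(split(xs, grp), mean, 0)
  present <- as.integer(names(sbp))
  keep <- present[ok[present]]
  sel <- match(keep, present)
  res <- data.frame(time = beat_times[keep], sbp = sbp[sel],
                    dbp = dbp[sel], mbp = mbp[sel], row.names = NULL)
  class(res) <- c("pressure_beats", "data.frame")
  res
}

#' Extract one pressure component as a beat series
#' @param pb a [extract_bp_beats()] result.
#' @param what `"sbp"`, `"dbp"` or `"mbp"`.
#' @export
pressure_series <- function(pb, what = c("sbp", "dbp", "mbp")) {
  what <- match.arg(what)
  stopifnot(inherits(pb, "pressure_beats"))
  beat_series(pb$time, pb[[what]], what, "mmHg")
}

# peak prominence on a short segment: height above the higher of the two
# bounding minima towards taller neighbours
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    m <- x[p]; j <- p
    while (j > 1 && x[j] <= x[p]) { j <- j - 1L; m <- min(m, x[j]) }
    left_base <- m
    m <- x[p]; j <- p
    while (j < n && x[j] <= x[p]) { j <- j + 1L; m <- min(m, x[j]) }
    right_base <- m
    x[p] - max(left_base, right_base)
  }, 0)
}

#' Respiratory frequency from tracheal pressure
#'
#' Splits the recording into non-overlapping windows and, in each, counts
#' dominant respiratory cycles by peak detection with a prominence floor of
#' 20% of the window's amplitude range. RF is `60 * (n_peaks - 1) / span`
#' where `span` is the first-to-last peak interval, i.e. cycles per minute
#' from complete cycles only.
#'
#' @param tracheal a [waveform()].
#' @param window_s window length, >= 10 s.
#' @param prominence_frac prominence floor as a fraction of the window's
#'   amplitude range.
#' @return A [beat_series()] (kind `"rf"`, cycles/min) timestamped at window
#'   centres, with attribute `quality` (`"ok"` or `"aperiodic"` per window).
#' @export
respiratory_frequency <- function(tracheal, window_s = 15,
                                  prominence_frac = 0.2) {
  stopifnot(inherits(tracheal, "waveform"))
  if (window_s < 10) stop("window_s must be >= 10 s")
  fs <- tracheal$sampling_rate
  x <- tracheal$samples
  wlen <- round(window_s * fs)
  nwin <- floor(length(x) / wlen)
  if (nwin < 1L) stop("recording shorter than one window")
  times <- values <- numeric(nwin)
  quality <- character(nwin)
  for (k in seq_len(nwin)) {
    seg <- x[((k - 1L) * wlen + 1L):(k * wlen)]
    rng <- diff(range(seg))
    pk <- local_maxima(seg)
    if (rng > 0 && length(pk)) {
      prom <- peak_prominences(seg, pk)
      pk <- pk[prom >= prominence_frac * rng]
    } else pk <- integer()
    if (length(pk) >= 2L) {
      span <- (pk[length(pk)] - pk[1L]) / fs
      values[k] <- 60 * (length(pk) - 1L) / span
      quality[k] <- "ok"
    } else {
      values[k] <- 0
      quality[k] <- "aperiodic"
    }
    times[k] <- tracheal$start_time + ((k - 1L) * wlen + wlen / 2) / fs
  }
  out <- beat_series(times, values, "rf", "cpm")
  attr(out, "quality") <- quality
  out
}
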