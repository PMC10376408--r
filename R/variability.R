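# Time-frequency cardiovascular variability: Morlet continuous wavelet
# transform band power of beat-indexed series over 3-min windows.

#' Frequency band definition
#'
#' Defaults follow the rat convention used throughout the package: LF
#' (0.15-0.6 Hz) measured on systolic blood pressure (sympathetic marker),
#' HF (0.6-2.0 Hz) measured on heart rate (respiratory-coupled,
#' parasympathetic marker).
#'
#' @param name `"LF"` or `"HF"` (free text allowed).
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @param source which series the band is computed on (`"SBP"` or `"HR"`).
#' @return An object of class `"band_definition"`.
#' @export
band_definition <- function(name, f_lo, f_hi, source = c("SBP", "HR")) {
  source <- match.arg(source)
  if (!(is.finite(f_lo) && is.finite(f_hi) && 0 < f_lo && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi, source = source),
            class = "band_definition")
}

#' Default LF and HF bands
#' @return list with elements `lf` and `hf`.
#' @export
default_bands <- function() {
  list(lf = band_definition("LF", 0.15, 0.6, "SBP"),
       hf = band_definition("HF", 0.6, 2.0, "HR"))
}

#' Resample a beat series onto a uniform grid
#'
#' Cubic-spline interpolation onto a regular grid spanning exactly the beat
#' series (no extrapolation), followed by mean removal -- the standard
#' preprocessing before spectral analysis of unevenly sampled beat-to-beat
#' data.
#'
#' @param series a [beat_series()] spanning at least 30 s.
#' @param fs_resample target rate in Hz, >= 4 (>= 2x the HF upper edge).
#' @return An object of class `"resampled_series"`: list with `values`,
#'   `fs`, `start_time`, `mean_removed = TRUE`, `mean_value`.
#' @export
resample_beat_series <- function(series, fs_resample = 10) {
  stopifnot(inherits(series, "beat_series"))
  span <- diff(range(series$times))
  if (span < 30)
    stop("series spans ", signif(span, 4),
         " s; at least 30 s are required for band-power analysis")
  if (fs_resample < 4) stop("fs_resample must be >= 4 Hz")
  f <- stats::splinefun(series$times, series$values, method = "fmm")
  grid <- seq(series$times[1L], series$times[length(series$times)],
              by = 1 / fs_resample)
  v <- f(grid)
  mu <- mean(v)
  structure(list(values = v - mu, fs = fs_resample, start_time = grid[1L],
                 mean_removed = TRUE, mean_value = mu),
            class = "resampled_series")
}

# Analytic Morlet CWT at the given frequencies (Hz). omega0 = 6 (standard
# HRV convention); scale-frequency relation f = omega0 / (2 pi s).
# Returns |W|^2 as an n_freq x n_time matrix, Torrence & Compo normalized.
cwt_morlet_power <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  # reflect-pad to soften edges, then round up to a power of two
  pad <- c(rev(x), x, rev(x))
  np <- length(pad)
  nfft <- 2^ceiling(log2(np))
  pad <- c(pad, rep(0, nfft - np))
  X <- stats::fft(pad)
  w <- 2 * pi * fs * c(0:(nfft / 2), -((nfft / 2 - 1):1)) / nfft
  out <- matrix(0, length(freqs), n)
  off <- n  # original signal occupies pad[(n+1):(2n)]
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi <- sqrt(2 * pi * s * fs) * pi^(-0.25) * exp(-((s * w - omega0)^2) / 2)
    psi[w < 0] <- 0        # analytic wavelet
    W <- stats::fft(X * psi, inverse = TRUE) / nfft
    out[k, ] <- Mod(W[(off + 1):(off + n)])^2
  }
  out
}

#' Wavelet band power of a uniformly resampled series
#'
#' Continuous wavelet transform with the analytic Morlet wavelet
#' (centre-frequency parameter 6); per-time band power is the integral of
#' squared magnitude over the scales mapped into `[f_lo, f_hi]`. The scaling
#' is fixed by calibration against a unit-amplitude sinusoid at the band's
#' geometric mid-frequency, so a unit in-band sinusoid yields mean power
#' 0.5 (i.e. band power equals signal variance for band-confined signals).
#' Samples inside the cone of influence of the band's largest scale are
#' excluded from `mean_power`.
#'
#' @param series a [resample_beat_series()] result.
#' @param band a [band_definition()].
#' @param n_voices scales per octave (default 16).
#' @param omega0 Morlet centre-frequency parameter.
#' @return list with `times_rel` (seconds from series start),
#'   `power_timecourse`, `mean_power`, `band`, and `coi` (logical: inside
#'   the cone of influence).
#' @export
wavelet_band_power <- function(series, band, n_voices = 16, omega0 = 6) {
  stopifnot(inherits(series, "resampled_series"),
            inherits(band, "band_definition"))
  fs <- series$fs
  n <- length(series$values)
  if (band$f_hi > fs / 2)
    stop("band upper edge ", band$f_hi, " Hz exceeds Nyquist ", fs / 2, " Hz")
  dur <- (n - 1) / fs
  if (dur < 5 / band$f_lo)
    stop("series of ", signif(dur, 4), " s is shorter than 5 cycles of ",
         band$f_lo, " Hz")
  n_oct <- log2(band$f_hi / band$f_lo)
  freqs <- band$f_lo * 2^(seq(0, n_oct, by = 1 / n_voices))
  pw <- cwt_morlet_power(series$values, fs, freqs, omega0)
  # trapezoid weights over log-spaced frequencies
  wts <- numeric(length(freqs))
  df <- diff(freqs)
  wts[1] <- df[1] / 2
  wts[length(freqs)] <- df[length(df)] / 2
  if (length(freqs) > 2)
    wts[2:(length(freqs) - 1)] <- (df[-length(df)] + df[-1]) / 2
  raw <- as.numeric(crossprod(wts, pw))
  # calibration: unit sinusoid at the geometric mid-band frequency -> 0.5
  f_mid <- sqrt(band$f_lo * band$f_hi)
  tt <- (seq_len(n) - 1) / fs
  ref <- sin(2 * pi * f_mid * tt)
  ref <- ref - mean(ref)
  pw_ref <- cwt_morlet_power(ref, fs, freqs, omega0)
  s_max <- omega0 / (2 * pi * band$f_lo)
  coi_s <- sqrt(2) * s_max
  coi <- tt < coi_s | tt > dur - coi_s
  if (all(coi)) coi <- rep(FALSE, n)  # degenerate short record: keep all
  ref_raw <- as.numeric(crossprod(wts, pw_ref))
  cal <- 0.5 / mean(ref_raw[!coi])
  power <- raw * cal
  list(times_rel = tt, power_timecourse = power,
       mean_power = mean(power[!coi]), band = band, coi = coi)
}

#' LF/HF ratio
#'
#' @param lf_power,hf_power band powers (same analysis window).
#' @param eps definedness floor for the denominator (default 1e-12).
#' @return `lf_power / hf_power`, or `NA` (with attribute
#'   `undefined = TRUE`) when `hf_power <= eps`.
#' @export
lf_hf_ratio <- function(lf_power, hf_power, eps = 1e-12) {
  stopifnot(is.finite(lf_power), lf_power >= 0, is.finite(hf_power))
  if (hf_power <= eps) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  lf_power / hf_power
}

#' Autonomic indices for one analysis window
#'
#' Computes LF power on the systolic-pressure beat series and HF power on
#' the heart-rate beat series over a single window (default 180 s, the
#' 3-min convention), plus their ratio -- the sympathovagal balance index.
#'
#' @param sbp systolic-pressure [beat_series()] (mmHg).
#' @param hr heart-rate [beat_series()] (bpm).
#' @param window_s analysis window length in seconds (default 180).
#' @param start_s window start (default: start of the overlapping span).
#' @param bands list with `lf` and `hf` [band_definition()]s.
#' @param fs_resample uniform resampling rate (Hz).
#' @return An object of class `"autonomic_indices"`: list with `window`
#'   (start_s, end_s), `lf_power` (mmHg^2), `hf_power` (bpm^2),
#'   `lf_hf_ratio` (NA with `ratio_undefined = TRUE` when HF power is below
#'   the definedness floor).
#' @export
analyze_window <- function(sbp, hr, window_s = 180, start_s = NULL,
                           bands = default_bands(), fs_resample = 10) {
  stopifnot(inherits(sbp, "beat_series"), inherits(hr, "beat_series"))
  lo <- max(min(sbp$times), min(hr$times))
  hi <- min(max(sbp$times), max(hr$times))
  clamp <- is.null(start_s)
  if (clamp) start_s <- lo
  end_s <- start_s + window_s
  if (clamp && end_s > hi) end_s <- hi  # default window shrinks to the span
  if (start_s < lo - 1e-9 || end_s > hi + 1e-9)
    stop("requested window [", start_s, ", ", end_s,
         "] s is not covered by both series (joint span [",
         signif(lo, 6), ", ", signif(hi, 6), "] s)")
  sbp_w <- beat_series_window(sbp, start_s, end_s)
  hr_w <- beat_series_window(hr, start_s, end_s)
  lf <- wavelet_band_power(resample_beat_series(sbp_w, fs_resample), bands$lf)
  hf <- wavelet_band_power(resample_beat_series(hr_w, fs_resample), bands$hf)
  ratio <- lf_hf_ratio(lf$mean_power, hf$mean_power)
  structure(list(window = c(start_s = start_s, end_s = end_s),
                 lf_power = lf$mean_power, hf_power = hf$mean_power,
                 lf_hf_ratio = as.numeric(ratio),
                 ratio_undefined = isTRUE(attr(ratio, "undefined")),
                 lf_timecourse = lf$power_timecourse,
                 hf_timecourse = hf$power_timecourse),
            class = "autonomic_indices")
}

#' @export
print.autonomic_indices <- function(x, ...) {
  cat(sprintf("<autonomic_indices> [%g, %g] s: LF %.4g mmHg^2, HF %.4g bpm^2, LF/HF %s\n",
              x$window["start_s"], x$window["end_s"], x$lf_power, x$hf_power,
              if (x$ratio_undefined) "undefined" else sprintf("%.4g", x$lf_hf_ratio)))
  invisible(x)
}
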