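# Independent oracles shared across test files.

# FFT periodogram band integral in the amplitude^2/2 convention: a unit
# sinusoid inside the band integrates to 0.5. Independent of the wavelet
# code path.
periodogram_band_power <- function(values, fs, f_lo, f_hi) {
  x <- values - mean(values)
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n^2 * 2
  f <- (seq_len(n) - 1) * fs / n
  sum(P[f >= f_lo & f <= f_hi & f <= fs / 2])
}

# uniform beat series for constructing analytic test signals
uniform_series <- function(f_hz, amp, duration_s = 180, dt = 0.16,
                           kind = "sbp", units = "mmHg", offset = 0) {
  tt <- seq(0, duration_s, by = dt)
  beat_series(tt, offset + amp * sin(2 * pi * f_hz * tt), kind, units)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
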