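# Provoked autonomic reflexes: baroreflex gain (phenylephrine) and
# chemoreflex sensitivity (lobeline).

#' Analysis windows around a reflex provocation
#'
#' Baseline is the 30 s immediately before the injection and the response
#' window the 60 s after it (peak-delta convention for a bolus stimulus);
#' both are configurable.
#'
#' @param injection_time_s injection event time (seconds).
#' @param stimulus `"phenylephrine"` or `"lobeline"`.
#' @param baseline_s,response_s window lengths in seconds.
#' @return An object of class `"reflex_window"`.
#' @export
reflex_window <- function(injection_time_s,
                          stimulus = c("phenylephrine", "lobeline"),
                          baseline_s = 30, response_s = 60) {
  stimulus <- match.arg(stimulus)
  if (baseline_s <= 0 || response_s <= 0)
    stop("baseline_s and response_s must be positive")
  if (injection_time_s - baseline_s < 0)
    stop("baseline window extends before the recording start")
  structure(list(
    baseline = c(start_s = injection_time_s - baseline_s,
                 end_s = injection_time_s),
    response = c(start_s = injection_time_s,
                 end_s = injection_time_s + response_s),
    stimulus = stimulus, injection_time_s = injection_time_s),
    class = "reflex_window")
}

#' Reflex window from a bundle's labelled event
#' @param bundle a [recording_bundle()].
#' @param stimulus event label to look up.
#' @param ... passed to [reflex_window()].
#' @export
reflex_window_from_bundle <- function(bundle,
                                      stimulus = c("phenylephrine",
                                                   "lobeline"), ...) {
  stimulus <- match.arg(stimulus)
  reflex_window(event_time(bundle, stimulus), stimulus = stimulus, ...)
}

series_mean_in <- function(bs, win) {
  v <- bs$values[bs$times >= win["start_s"] & bs$times <= win["end_s"]]
  if (!length(v)) stop("beat series does not cover window [",
                       win["start_s"], ", ", win["end_s"], "] s")
  mean(v)
}

# centred rolling mean over +/- half_s seconds on an unevenly sampled series
rolling_mean_beats <- function(bs, half_s = 2) {
  vapply(bs$times, function(t0)
    mean(bs$values[bs$times >= t0 - half_s & bs$times <= t0 + half_s]), 0)
}

#' Baroreflex gain from a phenylephrine trial
#'
#' Quantifies the reflex as `|dHR| / dBP`: the pressure delta is the peak of
#' the (2-s-smoothed) mean-pressure series in the response window minus the
#' baseline mean; the HR delta is the mean heart rate within +/- 2 s of that
#' same peak-pressure time minus the baseline mean. The gain is reported as
#' a magnitude in bpm/mmHg while the signed `delta_hr` retains the response
#' direction (negative for the expected bradycardia).
#'
#' @param mbp mean-pressure [beat_series()] (mmHg).
#' @param hr heart-rate [beat_series()] (bpm).
#' @param window a [reflex_window()] with stimulus `"phenylephrine"`.
#' @param min_delta_bp trials with a pressure rise at or below this value
#'   (default 2 mmHg) are rejected as failed provocations.
#' @param peak_halfwidth_s half-width of the smoothing / HR-matching window.
#' @return An object of class `"baroreflex_result"`: list with `delta_bp`,
#'   `delta_hr`, `gain`, `peak_time_s`, and the baseline means.
#' @export
baroreflex_gain <- function(mbp, hr, window, min_delta_bp = 2,
                            peak_halfwidth_s = 2) {
  stopifnot(inherits(mbp, "beat_series"), inherits(hr, "beat_series"),
            inherits(window, "reflex_window"))
  if (window$stimulus != "phenylephrine")
    stop("baroreflex_gain requires a phenylephrine window")
  bp_base <- series_mean_in(mbp, window$baseline)
  hr_base <- series_mean_in(hr, window$baseline)
  resp <- beat_series_window(mbp, window$response["start_s"],
                             window$response["end_s"])
  if (!length(resp$times)) stop("pressure series does not cover the response window")
  sm <- rolling_mean_beats(resp, peak_halfwidth_s)
  ipk <- which.max(sm)
  t_pk <- resp$times[ipk]
  delta_bp <- sm[ipk] - bp_base
  if (!is.finite(delta_bp) || delta_bp <= min_delta_bp)
    stop("failed provocation: pressure rise ", signif(delta_bp, 3),
         " mmHg is not above ", min_delta_bp, " mmHg")
  hr_pk <- hr$values[hr$times >= t_pk - peak_halfwidth_s &
                     hr$times <= t_pk + peak_halfwidth_s]
  if (!length(hr_pk)) stop("heart-rate series does not cover the pressure peak")
  delta_hr <- mean(hr_pk) - hr_base
  structure(list(delta_bp = delta_bp, delta_hr = delta_hr,
                 gain = abs(delta_hr) / delta_bp, peak_time_s = t_pk,
                 bp_baseline = bp_base, hr_baseline = hr_base),
            class = "baroreflex_result")
}

#' @export
print.baroreflex_result <- function(x, ...) {
  cat(sprintf("<baroreflex> dBP %.2f mmHg, dHR %+.2f bpm, gain %.4f bpm/mmHg\n",
              x$delta_bp, x$delta_hr, x$gain))
  invisible(x)
}

#' Chemoreflex sensitivity from a lobeline trial
#'
#' `dRF = RF_stimulation - RF_basal` (signed, cycles/min): the basal rate is
#' the mean respiratory frequency over the baseline window and the
#' stimulated rate the maximum windowed RF within the response window.
#'
#' @param rf respiratory-frequency [beat_series()] from
#'   [respiratory_frequency()] (one value per analysis window).
#' @param window a [reflex_window()] with stimulus `"lobeline"`.
#' @return An object of class `"chemoreflex_result"`: list with `rf_basal`,
#'   `rf_stim`, `delta_rf`.
#' @export
chemoreflex_delta <- function(rf, window) {
  stopifnot(inherits(rf, "beat_series"), inherits(window, "reflex_window"))
  if (window$stimulus != "lobeline")
    stop("chemoreflex_delta requires a lobeline window")
  in_resp <- rf$times >= window$response["start_s"] &
    rf$times <= window$response["end_s"]
  if (!any(in_resp))
    stop("response window shorter than one RF analysis window")
  rf_basal <- series_mean_in(rf, window$baseline)
  rf_stim <- max(rf$values[in_resp])
  structure(list(rf_basal = rf_basal, rf_stim = rf_stim,
                 delta_rf = rf_stim - rf_basal),
            class = "chemoreflex_result")
}

#' @export
print.chemoreflex_result <- function(x, ...) {
  cat(sprintf("<chemoreflex> RF %.2f -> %.2f cpm, dRF %+.2f cpm\n",
              x$rf_basal, x$rf_stim, x$delta_rf))
  invisible(x)
}

#' Regression-slope baroreflex estimator (sensitivity analysis)
#'
#' Alternative to the peak-delta convention: ordinary least-squares slope of
#' heart rate on mean pressure over the rising phase (response window),
#' reported as a magnitude. Off by default in the pipeline; exposed for
#' sensitivity analyses.
#'
#' @inheritParams baroreflex_gain
#' @return list with `gain` (|slope|, bpm/mmHg) and `slope` (signed).
#' @export
baroreflex_gain_regression <- function(mbp, hr, window) {
  stopifnot(inherits(window, "reflex_window"))
  bp <- beat_series_window(mbp, window$response["start_s"],
                           window$response["end_s"])
  hr_w <- beat_series_window(hr, window$response["start_s"],
                             window$response["end_s"])
  hr_at <- stats::approx(hr_w$times, hr_w$values, xout = bp$times,
                         rule = 2)$y
  fit <- stats::lm.fit(cbind(1, bp$values), hr_at)
  slope <- unname(fit$coefficients[2])
  list(gain = abs(slope), slope = slope)
}
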