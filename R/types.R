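#' Uniformly sampled physiological waveform
#'
#' The basic container for a single recorded channel: an ordered vector of
#' samples at a fixed sampling rate. The time base is implicit
#' (`start_time + (i - 1) / sampling_rate`); event times elsewhere in the
#' package are absolute seconds on the same clock.
#'
#' @param samples numeric vector of samples (mmHg for pressures, mV for ECG,
#'   cmH2O for tracheal pressure). Must contain at least 2 finite values.
#' @param sampling_rate sampling frequency in Hz, > 0.
#' @param channel_name channel label, e.g. `"ecg"`, `"abp"`, `"tracheal"`.
#' @param units unit string for the samples.
#' @param start_time time of the first sample in seconds (default 0).
#'
#' @return An object of class `"waveform"`: a list with elements `samples`,
#'   `sampling_rate`, `channel_name`, `units`, `start_time`.
#' @export
waveform <- function(samples, sampling_rate, channel_name = "signal",
                     units = "", start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("waveform needs at least 2 samples, got ", length(samples))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("waveform samples must all be finite (channel '", channel_name, "')")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_name = channel_name, units = units,
         start_time = as.numeric(start_time)),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s'> %d samples @ %g Hz (%.3f s)%s\n",
              x$channel_name, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Time axis of a waveform
#' @param wf a [waveform()].
#' @return numeric vector of sample times in seconds.
#' @export
waveform_times <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  wf$start_time + (seq_along(wf$samples) - 1) / wf$sampling_rate
}

#' Duration of a waveform in seconds
#' @param wf a [waveform()].
#' @export
waveform_duration <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  (length(wf$samples) - 1) / wf$sampling_rate
}

#' Event-indexed (beat-indexed) series
#'
#' Holds one value per cardiac beat (or per analysis window), timestamped in
#' seconds. Used for RR intervals, beat-to-beat heart rate, per-beat
#' pressures and windowed respiratory frequency; generally unevenly spaced.
#'
#' @param times strictly increasing numeric vector, seconds.
#' @param values numeric vector, same length as `times`.
#' @param kind label, e.g. `"rr"`, `"hr"`, `"sbp"`, `"mbp"`, `"rf"`.
#' @param units unit string (`"ms"`, `"bpm"`, `"mmHg"`, `"cpm"`).
#' @return An object of class `"beat_series"`.
#' @export
beat_series <- function(times, values, kind = "value", units = "") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("beat_series times must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("beat_series values must be finite")
  if (identical(kind, "rr") && any(values <= 0))
    stop("RR intervals must be positive")
  structure(list(times = times, values = values, kind = kind, units = units),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series '%s'> %d points over [%.2f, %.2f] s%s\n",
              x$kind, length(x$times),
              if (length(x$times)) min(x$times) else NA_real_,
              if (length(x$times)) max(x$times) else NA_real_,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Restrict a beat series to a time window
#' @param bs a [beat_series()].
#' @param start_s,end_s window bounds in seconds (inclusive).
#' @export
beat_series_window <- function(bs, start_s, end_s) {
  stopifnot(inherits(bs, "beat_series"))
  keep <- bs$times >= start_s & bs$times <= end_s
  beat_series(bs$times[keep], bs$values[keep], bs$kind, bs$units)
}

VALID_GROUPS <- c("CTL", "DOX8", "DOX16", "DOX20")

#' Multichannel recording with events and metadata
#'
#' Bundles the synchronously acquired channels of one acute experiment
#' (ECG, arterial blood pressure, tracheal pressure) with injection/window
#' events and subject metadata. Synthetic bundles additionally carry a
#' `truth` element (ground-truth beat times and per-beat values) used by the
#' recovery tests; loaders of real data leave it `NULL`.
#'
#' @param channels named list of [waveform()] objects.
#' @param events data frame with columns `label` (character) and `time`
#'   (seconds), or `NULL`.
#' @param subject_id subject identifier.
#' @param group one of `"CTL"`, `"DOX8"`, `"DOX16"`, `"DOX20"`.
#' @param truth optional list of generator ground truth.
#' @return An object of class `"recording_bundle"`.
#' @export
recording_bundle <- function(channels, events = NULL, subject_id = "s1",
                             group = "CTL", truth = NULL) {
  if (!length(channels) || !all(vapply(channels, inherits, TRUE, "waveform")))
    stop("channels must be a non-empty named list of waveform objects")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be named")
  group <- match.arg(group, VALID_GROUPS)
  if (is.null(events))
    events <- data.frame(label = character(), time = numeric())
  stopifnot(is.data.frame(events), all(c("label", "time") %in% names(events)))
  if (nrow(events)) {
    t0 <- min(vapply(channels, function(w) w$start_time, 0))
    t1 <- max(vapply(channels, function(w) w$start_time + waveform_duration(w), 0))
    if (any(events$time < t0 | events$time > t1))
      stop("event times must fall within the recorded time range [",
           signif(t0, 6), ", ", signif(t1, 6), "] s")
  }
  structure(list(channels = channels, events = events,
                 subject_id = subject_id, group = group, truth = truth),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> subject %s (%s): channels %s; %d event(s)%s\n",
              x$subject_id, x$group,
              paste(names(x$channels), collapse = ", "), nrow(x$events),
              if (!is.null(x$truth)) "; ground truth attached" else ""))
  invisible(x)
}

#' Time of a labelled event in a bundle
#' @param bundle a [recording_bundle()].
#' @param label event label, e.g. `"phenylephrine"`.
#' @export
event_time <- function(bundle, label) {
  stopifnot(inherits(bundle, "recording_bundle"))
  i <- which(bundle$events$label == label)
  if (!length(i)) stop("no event labelled '", label, "' in bundle")
  bundle$events$time[i[1L]]
}
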