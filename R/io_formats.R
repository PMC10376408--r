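#' Read one waveform channel from a CSV file
#'
#' The CSV dialect is fixed: comma-separated, `"."` decimal, UTF-8, with a
#' mandatory header row; one column per channel, header = channel name.
#' The sampling rate is not stored in the file and must be supplied.
#'
#' @param path CSV file path.
#' @param channel name of the column to read.
#' @param sampling_rate sampling rate in Hz.
#' @param units unit string to attach (default `""`).
#' @param start_time start time in seconds (default 0).
#' @return A [waveform()].
#' @export
read_waveform_csv <- function(path, channel, sampling_rate, units = "",
                              start_time = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!channel %in% names(df))
    stop("format error: column '", channel, "' not present in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  raw <- df[[channel]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) | !is.finite(x))
  if (length(bad))
    stop("parse error: non-numeric or non-finite value '", raw[bad[1L]],
         "' in column '", channel, "' at data row ", bad[1L])
  waveform(x, sampling_rate, channel_name = channel, units = units,
           start_time = start_time)
}

#' Write one or more waveforms to a CSV file
#'
#' All waveforms must share length (columns of one table, one column per
#' channel). Values are written in full precision so that
#' `read_waveform_csv()` reproduces them exactly.
#'
#' @param wf a [waveform()] or list of waveforms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  if (inherits(wf, "waveform")) wf <- list(wf)
  stopifnot(all(vapply(wf, inherits, TRUE, "waveform")))
  ns <- vapply(wf, function(w) length(w$samples), 0L)
  if (length(unique(ns)) != 1L)
    stop("all channels written to one CSV must have equal length")
  cols <- lapply(wf, function(w) format(w$samples, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  df <- as.data.frame(cols, check.names = FALSE)
  names(df) <- vapply(wf, function(w) w$channel_name, "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- EDF ------------------------------------------------------------------
# Minimal EDF codec (European Data Format, 16-bit). Implemented here because
# no EDF package is available in the target library; covers the subset this
# pipeline writes: one data record per second when the rate divides evenly,
# otherwise a single record holding the whole signal.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write waveforms to an EDF file
#'
#' Physical values are scaled onto the full 16-bit digital range per channel,
#' so a read-back agrees with the input to within one quantization step
#' `(phys_max - phys_min) / 65535`.
#'
#' @param wf a [waveform()] or list of waveforms (equal durations).
#' @param path output path.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_waveform_edf <- function(wf, path, patient = "X", recording = "X") {
  if (inherits(wf, "waveform")) wf <- list(wf)
  stopifnot(length(wf) >= 1L, all(vapply(wf, inherits, TRUE, "waveform")))
  ns <- length(wf)
  n <- vapply(wf, function(w) length(w$samples), 0L)
  fs <- vapply(wf, function(w) w$sampling_rate, 0)
  dur <- n / fs
  if (length(unique(round(dur, 9))) != 1L)
    stop("all channels in one EDF must span the same duration")
  # one record per second if every rate is a whole number and divides n,
  # else a single record with the full signal
  if (all(fs == round(fs)) && all(n %% fs == 0)) {
    n_rec <- as.integer(dur[1L]); rec_dur <- 1
    spr <- as.integer(fs)
  } else {
    n_rec <- 1L; rec_dur <- dur[1L]
    spr <- as.integer(n)
  }
  pmin_ <- pmax_ <- dmin_ <- dmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- wf[[i]]$samples
    lo <- min(x); hi <- max(x)
    if (hi == lo) hi <- lo + 1  # avoid zero span for constant channels
    pmin_[i] <- lo; pmax_[i] <- hi
    dmin_[i] <- -32768; dmax_[i] <- 32767
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }
  con <- file(path, "wb"); on.exit(close(con))
  hdr_len <- 256L + 256L * ns
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(patient, 80); wr(recording, 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(hdr_len, 8); wr("", 44); wr(n_rec, 8)
  wr(format(rec_dur, digits = 7), 8); wr(ns, 4)
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80)
  fields <- list(
    function(i) wf[[i]]$channel_name, function(i) "",
    function(i) wf[[i]]$units,
    function(i) format(pmin_[i], digits = 8),
    function(i) format(pmax_[i], digits = 8),
    function(i) format(dmin_[i]), function(i) format(dmax_[i]),
    function(i) "")
  for (k in seq_along(fields))
    for (i in seq_len(ns)) wr(fields[[k]](i), widths[k])
  for (i in seq_len(ns)) wr(spr[i], 8)   # samples per record
  for (i in seq_len(ns)) wr("", 32)      # reserved
  for (r in seq_len(n_rec))
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  invisible(path)
}

edf_read_header <- function(con) {
  rd <- function(w) {
    raw <- readBin(con, "raw", n = w)
    if (length(raw) < w) stop("format error: truncated EDF header")
    trimws(rawToChar(raw[raw != as.raw(0L)]))  # tolerate embedded nuls
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)
  hdr_len <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("format error: corrupt EDF header")
  field <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- field(16); field(80); dims <- field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin_ <- as.numeric(field(8)); dmax_ <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr)))
    stop("format error: corrupt EDF signal headers")
  list(patient = patient, recording = recording, hdr_len = hdr_len,
       n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       dims = dims, pmin = pmin_, pmax = pmax_, dmin = dmin_, dmax = dmax_,
       spr = spr)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel_name label of the signal to extract.
#' @return A [waveform()] carrying EDF physical values, the header sampling
#'   rate and the header dimension string as units.
#' @export
read_waveform_edf <- function(path, channel_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) < 256) stop("format error: file too small to be EDF")
  con <- file(path, "rb"); on.exit(close(con))
  h <- edf_read_header(con)
  i <- match(channel_name, h$labels)
  if (is.na(i))
    stop("lookup error: channel '", channel_name, "' not in file (has: ",
         paste(h$labels, collapse = ", "), ")")
  out <- numeric(h$n_rec * h$spr[i])
  pos <- 0L
  for (r in seq_len(h$n_rec)) {
    for (j in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = h$spr[j], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < h$spr[j]) stop("format error: truncated EDF data")
      if (j == i) {
        out[pos + seq_along(d)] <- d
        pos <- pos + length(d)
      }
    }
  }
  phys <- h$pmin[i] + (out - h$dmin[i]) *
    (h$pmax[i] - h$pmin[i]) / (h$dmax[i] - h$dmin[i])
  waveform(phys, h$spr[i] / h$rec_dur, channel_name = channel_name,
           units = h$dims[i])
}

# ---- result tables --------------------------------------------------------

#' Write a long-format results table to CSV
#'
#' Stable column order `(subject, group, variable, value, units)`; a
#' read-back with [read_results_table()] reproduces the input.
#'
#' @param results data frame with the five columns above (extra columns are
#'   dropped with a warning). [autonomic indices][analyze_window] may be
#'   passed directly and are expanded to LF/HF/LF-HF rows via
#'   [indices_to_rows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "autonomic_indices"))
    results <- indices_to_rows(results)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data frame")
  need <- c("subject", "group", "variable", "value", "units")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results table lacks column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(results), need)
  if (length(extra)) warning("dropping extra column(s): ",
                             paste(extra, collapse = ", "))
  df <- results[need]
  dup <- duplicated(df[c("subject", "variable")])
  if (any(dup)) stop("duplicate (subject, variable) pair: ",
                     df$subject[dup][1L], " / ", df$variable[dup][1L])
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path CSV path.
#' @return data frame `(subject, group, variable, value, units)`.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(subject = "character",
                                       group = "character",
                                       variable = "character",
                                       value = "numeric",
                                       units = "character"))
  need <- c("subject", "group", "variable", "value", "units")
  if (!all(need %in% names(df)))
    stop("format error: not a results table: ", path)
  df[need]
}

#' Expand autonomic indices into results-table rows
#' @param ai an object from [analyze_window()].
#' @param subject,group identifiers for the rows.
#' @export
indices_to_rows <- function(ai, subject = "s1", group = "CTL") {
  stopifnot(inherits(ai, "autonomic_indices"))
  data.frame(
    subject = subject, group = group,
    variable = c("lf_power", "hf_power", "lf_hf"),
    value = c(ai$lf_power, ai$hf_power,
              if (is.na(ai$lf_hf_ratio)) NA_real_ else ai$lf_hf_ratio),
    units = c("mmHg2", "bpm2", ""))
}
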