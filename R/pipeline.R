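# End-to-end study replica: simulate a cohort, run beats -> variability ->
# reflexes -> histology -> group statistics, and emit the result tables.

#' Human-equivalent dose from a rat cumulative dose
#'
#' Body-surface-area conversion for the rat: `mg/m^2 = 6 x mg/kg`,
#' reproducing the standard equivalences (8 -> 48, 16 -> 96, 20 -> 120).
#'
#' @param dose_mg_per_kg cumulative dose in mg/kg, >= 0 (vectorized).
#' @return dose in mg/m^2.
#' @export
dose_human_equivalent <- function(dose_mg_per_kg) {
  if (any(!is.finite(dose_mg_per_kg)) || any(dose_mg_per_kg < 0))
    stop("dose must be a non-negative number")
  dose_mg_per_kg * 6
}

#' Pipeline configuration
#'
#' @param design a [group_design()].
#' @param seed master seed; every stage derives its randomness from it.
#' @param baseline_s baseline recording length (s).
#' @param sampling_rate waveform sampling rate (Hz).
#' @param image_px histology image side (px); 0 disables histology.
#' @param window_s variability analysis window (s).
#' @param fs_resample beat-series resampling rate (Hz).
#' @param bands list of `lf`/`hf` [band_definition()]s.
#' @param thresholds a [stain_thresholds()].
#' @param welch use Welch t-tests for intergroup comparisons.
#' @param out_dir output directory for CSV/JSON artefacts (`NULL`: no files).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = group_design(), seed = 1,
                            baseline_s = 180, sampling_rate = 500,
                            image_px = 256, window_s = 180,
                            fs_resample = 10, bands = default_bands(),
                            thresholds = stain_thresholds(), welch = TRUE,
                            out_dir = NULL) {
  structure(list(design = design, seed = as.integer(seed),
                 baseline_s = baseline_s, sampling_rate = sampling_rate,
                 image_px = image_px, window_s = window_s,
                 fs_resample = fs_resample, bands = bands,
                 thresholds = thresholds, welch = welch, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys: `seed`, `baseline_s`, `sampling_rate`, `image_px`,
#' `window_s`, `fs_resample`, `welch`, `out_dir`, `groups`, `sd_scale`,
#' `lf_band` / `hf_band` (two-element `[f_lo, f_hi]`), and the
#' stain-threshold fields of [stain_thresholds()]. Unknown keys error.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  known <- c("seed", "baseline_s", "sampling_rate", "image_px", "window_s",
             "fs_resample", "welch", "out_dir", "groups", "sd_scale",
             "lf_band", "hf_band", "hue_lo", "hue_hi", "sat_min", "val_lo",
             "val_hi", "bg_val_min", "bg_sat_max")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  design <- group_design(groups = y$groups %||% VALID_GROUPS,
                         sd_scale = y$sd_scale %||% 1)
  bands <- default_bands()
  if (!is.null(y$lf_band))
    bands$lf <- band_definition("LF", y$lf_band[1], y$lf_band[2], "SBP")
  if (!is.null(y$hf_band))
    bands$hf <- band_definition("HF", y$hf_band[1], y$hf_band[2], "HR")
  th_args <- y[intersect(names(y), c("hue_lo", "hue_hi", "sat_min", "val_lo",
                                     "val_hi", "bg_val_min", "bg_sat_max"))]
  pipeline_config(design = design, seed = y$seed %||% 1,
                  baseline_s = y$baseline_s %||% 180,
                  sampling_rate = y$sampling_rate %||% 500,
                  image_px = y$image_px %||% 256,
                  window_s = y$window_s %||% 180,
                  fs_resample = y$fs_resample %||% 10,
                  bands = bands,
                  thresholds = do.call(stain_thresholds, th_args),
                  welch = y$welch %||% TRUE, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_subject <- function(subj, cfg) {
  out <- list(subject = subj$subject_id, group = subj$params$group)
  tryCatch({
    b <- subj$baseline
    peaks <- detect_r_peaks(b$channels$ecg)
    series <- rr_and_hr(peaks)
    pb <- extract_bp_beats(b$channels$abp, peaks)
    rf <- respiratory_frequency(b$channels$tracheal)
    out$hr_bpm <- mean(series$hr$values)
    out$sbp_mmHg <- mean(pb$sbp)
    out$dbp_mmHg <- mean(pb$dbp)
    out$mbp_mmHg <- mean(pb$mbp)
    out$rf_cpm <- mean(rf$values[attr(rf, "quality") == "ok"])
    ai <- analyze_window(pressure_series(pb, "sbp"), series$hr,
                         window_s = min(cfg$window_s,
                                        floor(diff(range(series$hr$times)))),
                         bands = cfg$bands, fs_resample = cfg$fs_resample)
    out$lf_power <- ai$lf_power
    out$hf_power <- ai$hf_power
    out$lf_hf <- ai$lf_hf_ratio
  }, error = function(e)
    stop("stage 'baseline' failed for subject ", subj$subject_id, ": ",
         conditionMessage(e)))
  tryCatch({
    ph <- subj$phenylephrine
    peaks <- detect_r_peaks(ph$channels$ecg)
    series <- rr_and_hr(peaks)
    pb <- extract_bp_beats(ph$channels$abp, peaks)
    win <- reflex_window_from_bundle(ph, "phenylephrine")
    br <- baroreflex_gain(pressure_series(pb, "mbp"), series$hr, win)
    out$brg <- br$gain
    out$delta_bp <- br$delta_bp
    out$delta_hr <- br$delta_hr
  }, error = function(e)
    stop("stage 'baroreflex' failed for subject ", subj$subject_id, ": ",
         conditionMessage(e)))
  tryCatch({
    lb <- subj$lobeline
    rf <- respiratory_frequency(lb$channels$tracheal)
    win <- reflex_window_from_bundle(lb, "lobeline",
                                     baseline_s = 45, response_s = 60)
    ch <- chemoreflex_delta(rf, win)
    out$delta_rf <- ch$delta_rf
    out$rf_basal <- ch$rf_basal
  }, error = function(e)
    stop("stage 'chemoreflex' failed for subject ", subj$subject_id, ": ",
         conditionMessage(e)))
  if (!is.null(subj$histology)) {
    tryCatch({
      q <- quantify_collagen(subj$histology$image,
                             thresholds = cfg$thresholds)
      out$fibrotic_pct <- q$fibrotic_pct
    }, error = function(e)
      stop("stage 'histology' failed for subject ", subj$subject_id, ": ",
           conditionMessage(e)))
  }
  out
}

#' Run the full study replica
#'
#' Simulates the configured cohort, analyses every subject (beat detection,
#' pressures, respiratory rate, wavelet LF/HF, both reflexes, collagen
#' quantification), appends the catecholamine tables, and runs the group
#' statistics for every variable: per-group mean +/- SEM, assumption
#' checks, one-way ANOVA with Dunnett comparisons against CTL, and pairwise
#' unpaired t-tests among the treated groups. With `out_dir` set, writes
#' `subjects.csv`, `summaries.csv`, `comparisons.csv` and `report.json`
#' (all headed by the seed).
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"study_report"`: list with `subjects` (per-
#'   subject variable table), `summaries`, `comparisons`,
#'   `threshold_dose_mg_per_kg` (lowest dose whose Dunnett comparison vs
#'   CTL is significant for both systolic pressure and heart rate; NA if
#'   none) and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$design, seed = config$seed,
                            baseline_s = config$baseline_s,
                            sampling_rate = config$sampling_rate,
                            image_px = config$image_px)
  rows <- lapply(cohort$subjects, analyze_subject, cfg = config)
  subjects <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(subjects) <- NULL
  cats <- cohort$catecholamines
  for (v in unique(cats$variable))
    subjects[[v]] <- cats$value[cats$variable == v][
      match(subjects$subject, cats$subject[cats$variable == v])]
  vars <- setdiff(names(subjects), c("subject", "group"))
  groups_present <- unique(subjects$group)
  summaries <- do.call(rbind, unlist(lapply(vars, function(v) {
    lapply(groups_present, function(g) {
      s <- summarize_group(subjects[[v]][subjects$group == g], g)
      data.frame(variable = v, group = g, n = s$n, mean = s$mean,
                 sem = s$sem)
    })
  }), recursive = FALSE))
  comparisons <- do.call(rbind, lapply(vars, function(v) {
    gl <- split(subjects[[v]], subjects$group)[groups_present]
    res <- list()
    if (length(gl) >= 2L && all(lengths(gl) >= 3L)) {
      res$assume <- cbind(variable = v, check_assumptions(gl)[
        , c("test", "groups", "statistic", "p_value", "marks")])
    }
    if ("CTL" %in% names(gl) && length(gl) >= 2L) {
      ad <- anova_dunnett(gl, "CTL")
      res$anova <- cbind(variable = v, ad$anova[
        , c("test", "groups", "statistic", "p_value", "marks")])
      res$dunnett <- cbind(variable = v, ad$dunnett[
        , c("test", "groups", "statistic", "p_value", "marks")])
    }
    trt <- setdiff(names(gl), "CTL")
    if (length(trt) >= 2L) {
      pairs <- utils::combn(trt, 2, simplify = FALSE)
      res$t <- do.call(rbind, lapply(pairs, function(pr) {
        r <- unpaired_t(gl[[pr[1]]], gl[[pr[2]]], welch = config$welch)
        r$groups <- paste(pr[1], "vs", pr[2])
        cbind(variable = v,
              r[, c("test", "groups", "statistic", "p_value", "marks")])
      }))
    }
    do.call(rbind, res)
  }))
  if (is.null(comparisons))
    comparisons <- data.frame(variable = character(), test = character(),
                              groups = character(), statistic = numeric(),
                              p_value = numeric(), marks = character())
  rownames(comparisons) <- NULL
  report <- structure(list(
    subjects = subjects, summaries = summaries, comparisons = comparisons,
    threshold_dose_mg_per_kg = threshold_dose(comparisons),
    provenance = list(seed = config$seed,
                      n_subjects = nrow(subjects),
                      sampling_rate = config$sampling_rate,
                      baseline_s = config$baseline_s,
                      package_version = as.character(utils::packageVersion("cvautonomics")))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

# the headline "threshold dose": lowest DOX group significant vs CTL for
# both systolic pressure and heart rate by Dunnett
threshold_dose <- function(comparisons) {
  if (is.null(comparisons) || !nrow(comparisons) ||
      !any(comparisons$test == "dunnett")) return(NA_real_)
  doses <- c(DOX8 = 8, DOX16 = 16, DOX20 = 20)
  sig <- function(v, g) {
    r <- comparisons$test == "dunnett" & comparisons$variable == v &
      startsWith(comparisons$groups, paste0(g, " "))
    any(comparisons$p_value[r] < 0.05, na.rm = TRUE)
  }
  for (g in names(doses))
    if (sig("sbp_mmHg", g) && sig("hr_bpm", g)) return(unname(doses[g]))
  NA_real_
}

#' Write a study report's tables to a directory
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# seed=%d", report$provenance$seed)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(report$subjects, "subjects.csv")
  wr(report$summaries, "summaries.csv")
  wr(report$comparisons, "comparisons.csv")
  jsonlite::write_json(
    list(threshold_dose_mg_per_kg = report$threshold_dose_mg_per_kg,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$provenance$n_subjects, "subjects; threshold dose:",
      x$threshold_dose_mg_per_kg, "mg/kg\n")
  sig <- x$comparisons[x$comparisons$test == "dunnett" &
                       x$comparisons$p_value < 0.05, ]
  if (nrow(sig)) {
    cat("significant Dunnett comparisons vs CTL:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-14s %-16s p = %.4g %s\n", sig$variable[i],
                  sig$groups[i], sig$p_value[i], sig$marks[i]))
  }
  invisible(x)
}
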