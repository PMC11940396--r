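#' Pipeline run configuration
#'
#' @param cohort A \code{\link{cohort_spec}}.
#' @param detector A \code{\link{detector_config}}.
#' @param classifier A \code{\link{classifier_config}}.
#' @param hrv An \code{\link{hrv_config}}.
#' @param mode \code{"rr_native"} (beat annotations pass straight to the
#'   classifier) or \code{"waveform"} (recordings are rendered to ECG,
#'   beats re-detected and P waves re-assessed before classification).
#' @param fs Render/detect sampling rate for waveform mode, Hz.
#' @param snr_db Rendered-trace signal-to-noise ratio, dB.
#' @param outdir Output directory for report CSV/JSON (\code{NULL}: no
#'   files written).
#' @param seed Overall run seed (propagated to cohort, rendering,
#'   expression simulation and induction bookkeeping).
#' @param hrv_freq Compute frequency-domain HRV per recording (slower).
#' @param log_level \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_spec(),
                       detector = detector_config(),
                       classifier = classifier_config(),
                       hrv = hrv_config(),
                       mode = c("rr_native", "waveform"),
                       fs = 1000, snr_db = 20,
                       outdir = NULL, seed = 1L,
                       hrv_freq = TRUE,
                       log_level = c("info", "quiet", "debug")) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(detector, "detector_config"),
            inherits(classifier, "classifier_config"),
            inherits(hrv, "hrv_config"))
  structure(list(cohort = cohort, detector = detector,
                 classifier = classifier, hrv = hrv,
                 mode = match.arg(mode), fs = fs, snr_db = snr_db,
                 outdir = outdir, seed = as.integer(seed),
                 hrv_freq = isTRUE(hrv_freq),
                 log_level = match.arg(log_level)),
            class = "run_config")
}

pipe_log <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]])
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...)))
}

#' Analyze one recording: detect (optionally), classify, burden, HRV
#'
#' @param rec An \code{\link{annotated_recording}}.
#' @param config A \code{\link{run_config}}.
#' @param seed Seed for waveform rendering noise.
#' @return List: labels, episodes, burden (\code{burden_summary}), hrv
#'   (\code{hrv_summary}), beat_times.
#' @export
analyze_recording <- function(rec, config = run_config(), seed = 1L) {
  if (config$mode == "waveform") {
    clean <- render_ecg(rec, fs = config$fs, noise_sd = 0)
    nsd <- noise_sd_for_snr(clean, config$snr_db)
    noisy <- render_ecg(rec, fs = config$fs, noise_sd = nsd, seed = seed)
    r_times <- detect_r_peaks(noisy$waveform, config$detector)
    pw <- assess_p_wave(noisy$waveform, r_times, cfg = config$detector)
    beat_times <- r_times
    p_present <- ifelse(pw$indeterminate, NA, pw$p_present)
    p_morph_match <- pw$p_morph_match
  } else {
    beat_times <- rec$beat_times
    p_present <- rec$p_present
    p_morph_match <- rec$p_morph_match
  }
  rr_ms <- diff(beat_times) * 1000
  labels <- classify_beats(rr_ms, p_present, p_morph_match,
                           config$classifier)
  episodes <- segment_episodes(labels, beat_times)
  burden <- burden_24h(episodes, labels, beat_times,
                       duration = rec$duration,
                       represents = rec$represents_s)
  nn <- exclude_non_normal(rr_series(beat_times), labels, config$hrv)
  hrv <- aggregate_recording(nn, config$hrv, freq = config$hrv_freq)
  list(labels = labels, episodes = episodes, burden = burden, hrv = hrv,
       beat_times = beat_times)
}

#' Run the full simulated study and assemble the report surface
#'
#' Simulate the cohort, run the per-recording analysis chain (optionally
#' through the waveform renderer and detector), compute per-animal
#' burdens and HRV, run the study's statistical layer, and simulate plus
#' analyze the gene-expression panel. Deterministic for a fixed seed.
#'
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{study_report}:
#'   \itemize{
#'   \item \code{per_recording}: tidy data frame (animal, arm, period,
#'     metric, value) covering burden and HRV metrics;
#'   \item \code{table1}: mean 24-h heart rate per group/period
#'     (mean +/- SEM) with Welch p per period;
#'   \item \code{trends}: within-group trend test per arm and metric
#'     (normality-gated repeated-measures ANOVA / Friedman);
#'   \item \code{table2}: HRV median [IQR] per group/period with
#'     Mann-Whitney p;
#'   \item \code{table3}: expression summary and Welch p per gene;
#'   \item \code{induction}: pacing inducibility summary for the AF arm;
#'   \item \code{seed}, \code{mode}.
#'   }
#'   When \code{config$outdir} is set, per-recording metrics, the report
#'   tables and a JSON report are written there.
#' @export
run_experiment <- function(config = run_config()) {
  cfg <- config
  cohort <- cfg$cohort
  pipe_log(cfg, "info", "simulating cohort (", cohort$n_control,
           " control + ", cohort$n_af, " AF animals)")
  recs <- generate_cohort(cohort)
  idx <- attr(recs, "index")
  rows <- list()
  results <- list()
  for (i in seq_len(nrow(idx))) {
    nm <- idx$name[i]
    pipe_log(cfg, "debug", "analyzing ", nm)
    res <- analyze_recording(recs[[nm]], cfg,
                             seed = derive_seed(cfg$seed, 900, i))
    results[[nm]] <- res
    b <- res$burden; h <- res$hrv
    met <- c(mean_hr_24h = b$mean_hr_24h, apbs_per_24h = b$apbs_per_24h,
             af_episodes_per_24h = b$af_episodes_per_24h,
             mean_af_duration = b$mean_af_duration,
             af_present = as.numeric(b$af_present),
             sdnn = h$sdnn, rmssd = h$rmssd, pnn5 = h$pnn,
             lf = h$lf, hf = h$hf, lf_hf = h$lf_hf)
    rows[[i]] <- data.frame(animal = idx$animal[i], arm = idx$arm[i],
                            period = idx$period[i], metric = names(met),
                            value = unname(met), stringsAsFactors = FALSE)
  }
  per_rec <- do.call(rbind, rows)
  per_rec$period <- factor(per_rec$period, levels = PERIOD_LABELS)

  wide <- function(metric, arm) {
    sub <- per_rec[per_rec$metric == metric & per_rec$arm == arm, ]
    stats::xtabs(value ~ animal + period, sub)
  }
  pull <- function(metric, arm, period)
    per_rec$value[per_rec$metric == metric & per_rec$arm == arm &
                    per_rec$period == period]

  # table 1: mean HR per group/period, Welch p
  t1 <- do.call(rbind, lapply(PERIOD_LABELS, function(p) {
    af <- pull("mean_hr_24h", "af", p); ct <- pull("mean_hr_24h", "control", p)
    pv <- if (length(af) >= 2 && length(ct) >= 2) welch_t(af, ct)$p else NA
    data.frame(period = p,
               af_mean = mean(af), af_sem = stats::sd(af) / sqrt(length(af)),
               control_mean = mean(ct),
               control_sem = stats::sd(ct) / sqrt(length(ct)),
               p = pv, stringsAsFactors = FALSE)
  }))

  # within-group trends (fig 3 / fig 4 surface)
  trend_metrics <- c("mean_hr_24h", "apbs_per_24h", "af_episodes_per_24h",
                     "sdnn", "rmssd", "pnn5", "lf", "hf", "lf_hf")
  trends <- list()
  for (arm in c("control", "af")) {
    n_arm <- if (arm == "af") cohort$n_af else cohort$n_control
    if (n_arm < 3) next
    for (m in trend_metrics) {
      w <- wide(m, arm)
      if (!nrow(w) || any(!is.finite(w))) next
      tr <- within_group_trend(w)
      trends[[paste(arm, m, sep = ".")]] <- tr
    }
  }
  trend_tab <- do.call(rbind, lapply(names(trends), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(arm = parts[1], metric = parts[2],
               method = trends[[k]]$method,
               statistic = trends[[k]]$statistic, p = trends[[k]]$p,
               stringsAsFactors = FALSE)
  }))

  # table 2: HRV median [IQR] per group/period + Mann-Whitney p
  hrv_metrics <- c("sdnn", "rmssd", "pnn5", "lf", "hf", "lf_hf")
  t2 <- list()
  for (m in hrv_metrics) {
    for (p in PERIOD_LABELS) {
      af <- pull(m, "af", p); ct <- pull(m, "control", p)
      if (!length(af) || !length(ct) || any(!is.finite(c(af, ct)))) next
      pv <- if (length(af) >= 2 && length(ct) >= 2) mann_whitney(af, ct)$p
            else NA
      qa <- stats::quantile(af, c(0.25, 0.5, 0.75))
      qc <- stats::quantile(ct, c(0.25, 0.5, 0.75))
      t2[[length(t2) + 1L]] <- data.frame(
        metric = m, period = p,
        af_median = qa[2], af_q1 = qa[1], af_q3 = qa[3],
        control_median = qc[2], control_q1 = qc[1], control_q3 = qc[3],
        p = pv, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  t2 <- if (length(t2)) do.call(rbind, t2) else NULL

  # table 3: expression panel
  expr_raw <- simulate_expression(n_af = cohort$n_af,
                                  n_control = cohort$n_control,
                                  seed = derive_seed(cfg$seed, 33))
  expr <- relative_expression(expr_raw)

  # pacing inducibility bookkeeping for the AF arm
  outcomes <- simulate_induction_outcomes(stimulation_protocol(),
                                          n_animals = max(cohort$n_af, 1),
                                          seed = derive_seed(cfg$seed, 44))
  induction <- inducibility(outcomes)

  report <- structure(
    list(per_recording = per_rec, table1 = t1, trends = trend_tab,
         trend_tests = trends, table2 = t2,
         table3 = expr$summary, expression = expr, induction = induction,
         seed = cfg$seed, mode = cfg$mode),
    class = "study_report")

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_rec, file.path(cfg$outdir, "per_recording.csv"),
                     row.names = FALSE)
    utils::write.csv(t1, file.path(cfg$outdir, "table1_heart_rate.csv"),
                     row.names = FALSE)
    if (!is.null(trend_tab))
      utils::write.csv(trend_tab, file.path(cfg$outdir, "trends.csv"),
                       row.names = FALSE)
    if (!is.null(t2))
      utils::write.csv(t2, file.path(cfg$outdir, "table2_hrv.csv"),
                       row.names = FALSE)
    utils::write.csv(expr$summary, file.path(cfg$outdir,
                                             "table3_expression.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      report_json(report), file.path(cfg$outdir, "report.json"),
      auto_unbox = TRUE, digits = 10)
    pipe_log(cfg, "info", "report written to ", cfg$outdir)
  }
  report
}

# serializable summary of a study report
report_json <- function(report) {
  list(seed = report$seed, mode = report$mode,
       table1 = report$table1, trends = report$trends,
       table2 = report$table2, table3 = report$table3,
       induction = list(
         pct_animals_inducible = report$induction$pct_animals_inducible,
         cycle_inducibility_mean = report$induction$cycle_inducibility_mean,
         cycle_inducibility_sem = report$induction$cycle_inducibility_sem))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$seed, "mode", x$mode, "\n")
  cat("Mean 24-h heart rate (bpm):\n")
  print(x$table1, digits = 4)
  if (!is.null(x$trends)) {
    cat("\nWithin-group trends:\n")
    print(x$trends, digits = 4)
  }
  invisible(x)
}

#' Generate seeded test fixtures
#'
#' Writes versioned, seeded fixture recordings (plus MD5 checksums) used
#' by the test-suite and for quick experimentation. \code{"tiny"} is a
#' 2+2-animal cohort of 120-s recordings; \code{"desk"} is the full
#' default study (5+7 animals, 1-h compressed recordings).
#'
#' @param scale \code{"tiny"} or \code{"desk"}.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Path of the fixture directory, invisibly.
#' @export
make_fixtures <- function(scale = c("tiny", "desk"), dir = tempfile("fixtures"),
                          seed = 20260101L) {
  scale <- match.arg(scale)
  spec <- if (scale == "tiny") {
    cohort_spec(n_control = 2, n_af = 2,
                periods_control = default_period_specs("control", 120, 7200),
                periods_af = default_period_specs("af", 120, 7200),
                seed = seed)
  } else {
    cohort_spec(seed = seed)
  }
  recs <- generate_cohort(spec)
  write_cohort(recs, dir)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- substring(names(sums), nchar(dir) + 2)
  utils::write.csv(data.frame(file = names(sums), md5 = unname(sums)),
                   file.path(dir, "checksums.csv"), row.names = FALSE)
  invisible(dir)
}
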