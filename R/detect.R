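#' Detector configuration
#'
#' Defaults are rat-scaled: band-pass 10-80 Hz around the narrow rat QRS,
#' 60 ms refractory (safe below 1000 bpm), and a 20 ms moving-window
#' integrator, in the spirit of derivative/adaptive-threshold QRS
#' detectors.
#'
#' @param bandpass Length-2 band edges, Hz.
#' @param refractory Minimum inter-detection spacing, ms.
#' @param threshold_decay Fraction by which the running signal/noise peak
#'   estimates are updated per accepted peak (adaptive threshold memory).
#' @param p_search_window Window before QRS onset searched for a P wave, ms.
#' @param p_presence_threshold Normalized correlation above which a P wave
#'   counts as present.
#' @param p_morph_threshold Correlation below which a present P wave counts
#'   as morphologically different from sinus.
#' @return An object of class \code{detector_config}.
#' @export
detector_config <- function(bandpass = c(10, 80),
                            refractory = 60,
                            threshold_decay = 0.125,
                            p_search_window = 70,
                            p_presence_threshold = 0.5,
                            p_morph_threshold = 0.8) {
  stopifnot(length(bandpass) == 2, bandpass[1] > 0, bandpass[2] > bandpass[1],
            refractory > 0, p_search_window > 0,
            threshold_decay > 0, threshold_decay <= 1)
  structure(list(bandpass = bandpass, refractory = refractory,
                 threshold_decay = threshold_decay,
                 p_search_window = p_search_window,
                 p_presence_threshold = p_presence_threshold,
                 p_morph_threshold = p_morph_threshold),
            class = "detector_config")
}

#' Detect R peaks in a rendered waveform
#'
#' Band-pass filter, differentiate, square, moving-window integrate, then
#' adaptive two-level thresholding (running signal- and noise-peak
#' estimates) with a refractory period; detected peaks are refined to the
#' local extremum of the band-passed trace.
#'
#' @param waveform List with \code{samples} (mV) and \code{fs} (Hz), e.g.
#'   \code{rec$waveform} from \code{\link{render_ecg}}.
#' @param cfg A \code{\link{detector_config}}.
#' @return Numeric vector of R-peak times, seconds. A flat or non-finite
#'   signal yields an empty result with a warning.
#' @export
detect_r_peaks <- function(waveform, cfg = detector_config()) {
  fs <- waveform$fs
  x <- waveform$samples
  if (fs < 500) stop("fs must be >= 500 Hz")
  if (any(!is.finite(x))) {
    warning("non-finite samples: no detections")
    return(numeric(0))
  }
  if (length(x) < fs || stats::sd(x) == 0) {
    warning("flat or too-short signal: no detections")
    return(numeric(0))
  }
  bf <- signal::butter(2, cfg$bandpass / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  env <- c(0, diff(bp))^2
  w <- max(3L, round(0.020 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  # candidate local maxima of the integrated energy
  dd <- diff(env)
  cand <- which(dd[-length(dd)] > 0 & dd[-1] <= 0) + 1L
  if (!length(cand)) return(numeric(0))
  # adaptive two-level threshold (running signal / noise peak estimates)
  init <- stats::quantile(env[cand], 0.95, names = FALSE)
  spk <- init; npk <- stats::quantile(env[cand], 0.5, names = FALSE)
  dec <- cfg$threshold_decay
  refr <- cfg$refractory / 1000 * fs
  acc <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npk + 0.25 * (spk - npk)
    if (env[i] >= thr) {
      if (i - last < refr) {
        # within refractory: keep the larger of the two
        if (length(acc) && env[i] > env[acc[length(acc)]]) {
          acc[length(acc)] <- i; last <- i
          spk <- (1 - dec) * spk + dec * env[i]
        }
      } else {
        acc <- c(acc, i); last <- i
        spk <- (1 - dec) * spk + dec * env[i]
      }
    } else {
      npk <- (1 - dec) * npk + dec * env[i]
    }
  }
  if (!length(acc)) return(numeric(0))
  # refine to the extremum of the band-passed trace near each energy peak
  half <- round(0.015 * fs)
  r_idx <- vapply(acc, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory after refinement
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    while (!all(keep)) {
      drop <- which(!keep)[1]
      if (env[r_idx[drop]] > env[r_idx[drop - 1]]) r_idx <- r_idx[-(drop - 1)]
      else r_idx <- r_idx[-drop]
      keep <- c(TRUE, diff(r_idx) >= refr)
    }
  }
  (r_idx - 1L) / fs
}

#' Learn a sinus P-wave template from detected beats
#'
#' Averages the pre-QRS window of beats whose neighbouring RR intervals
#' are within 10 percent of the recording's median RR (a proxy for
#' confirmed sinus beats), after aligning each window.
#'
#' @param waveform List with \code{samples}, \code{fs}.
#' @param r_times Detected (or known) R-peak times, s.
#' @param cfg A \code{\link{detector_config}}.
#' @param max_beats Maximum number of beats averaged.
#' @return Numeric template vector (mV), with attribute \code{"fs"}.
#' @export
learn_p_template <- function(waveform, r_times, cfg = detector_config(),
                             max_beats = 100) {
  fs <- waveform$fs
  rr <- diff(r_times)
  med <- stats::median(rr)
  ok <- c(FALSE, abs(rr - med) < 0.1 * med) &
    c(abs(rr - med) < 0.1 * med, FALSE)
  idx <- which(ok)
  if (length(idx) < 10)
    stop("need >= 10 regular (sinus) beats to learn a P template")
  idx <- idx[seq_len(min(max_beats, length(idx)))]
  win <- p_window_idx(fs, cfg)
  segs <- vapply(idx, function(i) {
    c0 <- round(r_times[i] * fs) + 1L
    s <- c0 + win
    if (s[1] < 1) rep(NA_real_, length(win)) else waveform$samples[s]
  }, numeric(length(win)))
  tpl <- rowMeans(segs, na.rm = TRUE)
  tpl <- tpl - mean(tpl)
  attr(tpl, "fs") <- fs
  tpl
}

# index offsets (relative to the R sample) of the P search window:
# from -p_search_window ms up to -15 ms before the R peak
p_window_idx <- function(fs, cfg) {
  seq(-round(cfg$p_search_window / 1000 * fs), -round(0.015 * fs))
}

#' Assess P-wave presence and morphology per beat
#'
#' For each beat the pre-QRS window is compared with the sinus P template
#' by maximum normalized cross-correlation over small lags. To keep the
#' preceding beat's T wave out of the comparison at rapid rates, the
#' window is truncated so it starts no earlier than 60 ms after the
#' preceding R peak. A P wave is present when the absolute correlation
#' reaches \code{p_presence_threshold} and the window carries non-null
#' P-band amplitude (absolute matched-filter amplitude at least half the
#' template's own); a present P whose signed correlation falls below
#' \code{p_morph_threshold} (e.g. an inverted ectopic P) is flagged as a
#' morphology mismatch.
#'
#' @param waveform List with \code{samples}, \code{fs}.
#' @param r_times R-peak times, s.
#' @param sinus_p_template Template from \code{\link{learn_p_template}}
#'   (learned automatically when \code{NULL}).
#' @param cfg A \code{\link{detector_config}}.
#' @return Data frame with one row per beat: \code{r_time},
#'   \code{p_present}, \code{p_corr}, \code{p_morph_match},
#'   \code{indeterminate} (window ran off the recording start).
#' @export
assess_p_wave <- function(waveform, r_times, sinus_p_template = NULL,
                          cfg = detector_config()) {
  fs <- waveform$fs
  if (is.null(sinus_p_template))
    sinus_p_template <- learn_p_template(waveform, r_times, cfg)
  tpl_full <- as.numeric(sinus_p_template)
  win <- p_window_idx(fs, cfg)
  lags <- -round(0.010 * fs):round(0.010 * fs)
  n <- length(waveform$samples)
  t_guard <- round(0.060 * fs)  # clearance after the preceding R peak
  out <- data.frame(r_time = r_times, p_present = FALSE, p_corr = NA_real_,
                    p_morph_match = FALSE, indeterminate = FALSE)
  for (b in seq_along(r_times)) {
    c0 <- round(r_times[b] * fs) + 1L
    # truncate the search window to clear the previous beat's T wave
    min_off <- min(win)
    if (b > 1) {
      prev_off <- round((r_times[b - 1] - r_times[b]) * fs)
      min_off <- max(min_off, prev_off + t_guard)
    }
    sel <- win >= min_off
    if (sum(sel) < round(0.020 * fs)) {  # window too short to judge
      out$indeterminate[b] <- TRUE
      next
    }
    wsel <- win[sel]
    tpl <- tpl_full[sel]
    tpl <- tpl - mean(tpl)
    tpl_energy <- sum(tpl^2)
    span <- c0 + c(min(wsel) + min(lags), max(wsel) + max(lags))
    if (span[1] < 1 || span[2] > n || tpl_energy == 0) {
      out$indeterminate[b] <- TRUE
      next
    }
    best_r <- 0; best_a <- 0
    for (L in lags) {
      w <- waveform$samples[c0 + wsel + L]
      w <- w - mean(w)
      denom <- sqrt(sum(w^2) * tpl_energy)
      if (denom == 0) next
      r <- sum(w * tpl) / denom
      if (abs(r) > abs(best_r)) {
        best_r <- r
        best_a <- sum(w * tpl) / tpl_energy  # matched-filter amplitude
      }
    }
    out$p_corr[b] <- best_r
    amp_ok <- abs(best_a) >= 0.5
    out$p_present[b] <- isTRUE(abs(best_r) >= cfg$p_presence_threshold && amp_ok)
    out$p_morph_match[b] <- out$p_present[b] &&
      best_r >= cfg$p_morph_threshold
  }
  out
}
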