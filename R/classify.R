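#' Classifier configuration
#'
#' Operationalizes the study's qualitative arrhythmia definitions. AF
#' requires at least three consecutive beats with absent P waves (fixed by
#' definition) that are rapid (median run RR below \code{af_rapid_factor}
#' times the local sinus median RR) and irregular (RR coefficient of
#' variation above \code{af_irregularity_cv}). An APB is a premature beat
#' (RR below \code{apb_prematurity_factor} times the running sinus median)
#' whose P morphology differs from sinus.
#'
#' @param min_af_beats Minimum consecutive beats for AF; fixed at >= 3.
#' @param af_rapid_factor Rapidity threshold, fraction of sinus median RR.
#' @param af_irregularity_cv Minimum within-run RR CV.
#' @param apb_prematurity_factor Prematurity threshold, fraction of the
#'   running sinus median RR.
#' @param sinus_median_window Sliding window (beats) for the local sinus
#'   median RR.
#' @param artifact_rr_floor_ms RR below this is physiologically impossible
#'   and flags an artifact, ms.
#' @return An object of class \code{classifier_config}.
#' @export
classifier_config <- function(min_af_beats = 3,
                              af_rapid_factor = 0.75,
                              af_irregularity_cv = 0.08,
                              apb_prematurity_factor = 0.85,
                              sinus_median_window = 11,
                              artifact_rr_floor_ms = 40) {
  if (min_af_beats < 3)
    stop("min_af_beats must be >= 3: AF is at least three consecutive beats")
  for (f in c(af_rapid_factor, apb_prematurity_factor))
    if (!is.finite(f) || f <= 0 || f >= 1)
      stop("rapidity/prematurity factors must lie in (0, 1)")
  stopifnot(af_irregularity_cv > 0, sinus_median_window >= 3)
  structure(list(min_af_beats = as.integer(min_af_beats),
                 af_rapid_factor = af_rapid_factor,
                 af_irregularity_cv = af_irregularity_cv,
                 apb_prematurity_factor = apb_prematurity_factor,
                 sinus_median_window = as.integer(sinus_median_window),
                 artifact_rr_floor_ms = artifact_rr_floor_ms),
            class = "classifier_config")
}

#' Classify beats into sinus / APB / AF / artifact
#'
#' Applies the study's definitions to a beat sequence described by RR
#' intervals and per-beat P-wave flags. Maximal runs of absent-P beats are
#' AF when they span at least \code{min_af_beats} beats, their median RR
#' is below \code{af_rapid_factor} times the local sinus median RR, and
#' their RR CV exceeds \code{af_irregularity_cv}; absent-P runs failing
#' the AF criteria are labeled APB beat-by-beat (every arrhythmic beat
#' stays accounted for). Isolated premature beats with a P of non-sinus
#' morphology are APBs. Beats with physiologically impossible RR are
#' artifacts.
#'
#' @param rr RR intervals in ms, length \code{n - 1} for \code{n} beats
#'   (RR[i] precedes beat i+1).
#' @param p_present Logical per beat (length n). \code{NA} (indeterminate)
#'   is treated as absent-P when flanked by absent-P beats and as sinus-P
#'   otherwise.
#' @param p_morph_match Logical per beat (length n).
#' @param cfg A \code{\link{classifier_config}}.
#' @return Character vector of per-beat labels (length n).
#' @export
classify_beats <- function(rr, p_present, p_morph_match,
                           cfg = classifier_config()) {
  n <- length(p_present)
  if (length(rr) != n - 1)
    stop("rr must have length(p_present) - 1")
  if (length(p_morph_match) != n)
    stop("p_morph_match must align with p_present")
  if (n < cfg$min_af_beats + 1)
    stop("need at least min_af_beats + 1 beats to classify")
  # resolve indeterminate P flags by local context
  pp <- p_present
  na_idx <- which(is.na(pp))
  for (i in na_idx) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    nb <- pp[c(lo, hi)]
    pp[i] <- !any(!nb, na.rm = TRUE)  # absent if any neighbour absent
  }
  pp[is.na(pp)] <- TRUE
  # bridge isolated present-P calls inside absent-P runs: a single-beat P
  # "detection" flanked by absent-P beats on both sides is spurious
  if (n >= 3) {
    iso <- which(pp[2:(n - 1)] & !pp[1:(n - 2)] & !pp[3:n]) + 1L
    pp[iso] <- FALSE
  }
  rr_prev <- c(NA, rr)  # rr_prev[i] = interval ending at beat i
  labels <- rep("sinus", n)
  # artifacts: impossible RR
  labels[!is.na(rr_prev) & rr_prev < cfg$artifact_rr_floor_ms] <- "artifact"
  # provisional sinus = P present & morphology match; used for the
  # local reference RR
  sinus_like <- pp & !labels %in% "artifact"
  sinus_rr <- rr[sinus_like[-n] & sinus_like[-1]]  # both bounding beats
  global_med <- if (length(sinus_rr)) stats::median(sinus_rr)
                else stats::median(rr)
  if (!length(sinus_rr))
    warning("no sinus reference intervals; using global median RR")
  # local sinus median before index i (sliding window of sinus intervals)
  sinus_int_end <- which(sinus_like[-n] & sinus_like[-1]) + 1L  # beat index
  local_median <- function(i) {
    prev <- sinus_int_end[sinus_int_end <= i]
    if (length(prev) < 3) return(global_med)
    k <- utils::tail(prev, cfg$sinus_median_window)
    stats::median(rr[k - 1L])
  }
  # maximal absent-P runs
  r <- rle(!pp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    len <- i1 - i0 + 1L
    run_rr <- if (i1 > i0) rr[i0:(i1 - 1L)] else numeric(0)
    run_rr <- run_rr[is.finite(run_rr)]
    ref <- local_median(i0)
    is_af <- len >= cfg$min_af_beats &&
      length(run_rr) >= 2 &&
      stats::median(run_rr) < cfg$af_rapid_factor * ref &&
      stats::sd(run_rr) / mean(run_rr) > cfg$af_irregularity_cv
    lab <- if (is_af) "af" else "apb"
    seg <- i0:i1
    labels[seg][labels[seg] != "artifact"] <- lab
  }
  # isolated premature beats with mismatched P morphology
  iso <- which(pp & !p_morph_match & labels == "sinus")
  for (i in iso) {
    if (is.na(rr_prev[i])) next
    if (rr_prev[i] < cfg$apb_prematurity_factor * local_median(i))
      labels[i] <- "apb"
  }
  labels
}

#' Segment labeled beats into arrhythmic episodes
#'
#' Maximal runs of AF-labeled beats become AF episodes; following the
#' study convention, an episode runs from its first arrhythmic beat to the
#' first subsequent sinus beat (recording end when none follows). APB
#' beats become single-beat episodes.
#'
#' @param labels Per-beat labels from \code{\link{classify_beats}}.
#' @param beat_times Beat times, seconds (aligned with labels).
#' @return Data frame with columns start_s, end_s, type, n_beats,
#'   duration_s; zero rows when no arrhythmic beats exist.
#' @export
segment_episodes <- function(labels, beat_times) {
  stopifnot(length(labels) == length(beat_times))
  out <- list()
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(labels)
  for (j in seq_along(r$values)) {
    if (r$values[j] == "af") {
      i0 <- starts[j]; i1 <- ends[j]
      after <- which(labels == "sinus" & seq_len(n) > i1)
      end_s <- if (length(after)) beat_times[after[1]] else beat_times[n]
      out[[length(out) + 1L]] <- data.frame(
        start_s = beat_times[i0], end_s = end_s, type = "af",
        n_beats = i1 - i0 + 1L, stringsAsFactors = FALSE)
    } else if (r$values[j] == "apb") {
      for (i in starts[j]:ends[j])
        out[[length(out) + 1L]] <- data.frame(
          start_s = beat_times[i], end_s = beat_times[i], type = "apb",
          n_beats = 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    ep <- empty_episodes()
    ep$duration_s <- numeric(0)
    return(ep)
  }
  ep <- do.call(rbind, out)
  ep$duration_s <- ep$end_s - ep$start_s
  stopifnot(all(ep$n_beats[ep$type == "af"] >= 3))
  ep[order(ep$start_s), , drop = FALSE]
}

#' Per-recording arrhythmic burden, normalized to 24 h
#'
#' Counts are scaled by \code{86400 / represents}; mean heart rate uses
#' the actual beat span. With a time-compressed recording (one that
#' stands for a longer telemetry interval), pass the represented time so
#' burdens stay on the study's per-24h scale; episode durations are
#' likewise converted to represented seconds (the generator compresses
#' placed durations by the same factor).
#'
#' @param episodes Episode data frame from \code{\link{segment_episodes}}.
#' @param labels Per-beat labels.
#' @param beat_times Beat times, seconds.
#' @param duration Actual recording duration, s (> 0).
#' @param represents Represented telemetry time, s (default: duration).
#' @return List of class \code{burden_summary}: mean_hr_24h (bpm),
#'   apbs_per_24h, af_episodes_per_24h, mean_af_duration (s), af_present.
#' @export
burden_24h <- function(episodes, labels, beat_times, duration,
                       represents = duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  scale <- 86400 / represents
  af_eps <- episodes[episodes$type == "af", , drop = FALSE]
  n_apb <- sum(episodes$type == "apb")
  structure(list(
    mean_hr_24h = 60 * max(0L, length(beat_times) - 1L) / duration,
    apbs_per_24h = n_apb * scale,
    af_episodes_per_24h = nrow(af_eps) * scale,
    mean_af_duration = if (nrow(af_eps))
      mean(af_eps$duration_s) * represents / duration else 0,
    af_present = nrow(af_eps) > 0), class = "burden_summary")
}

#' Pacing inducibility metrics
#'
#' Per animal: percentage of stimulation cycles followed by an AF episode
#' and whether any cycle induced AF. Cohort level: percentage of animals
#' inducible (one decimal) and mean +/- SEM of per-animal cycle
#' inducibility.
#'
#' @param cycle_outcomes List of logical vectors, one per animal (TRUE =
#'   the cycle was followed by an AF episode). An attribute
#'   \code{"durations"} (list of induced-episode durations, s) is summarized
#'   when present.
#' @return List of class \code{inducibility_summary}: \code{per_animal}
#'   data frame (n_cycles, n_induced, cycle_inducibility_pct,
#'   animal_inducible), \code{pct_animals_inducible},
#'   \code{cycle_inducibility_mean}, \code{cycle_inducibility_sem},
#'   \code{induced_af_duration_mean}, \code{induced_af_duration_sd}.
#' @examples
#' # six of seven animals with at least one induced episode -> 85.7%
#' out <- inducibility(c(rep(list(c(TRUE, FALSE, FALSE)), 6),
#'                       list(c(FALSE, FALSE, FALSE))))
#' out$pct_animals_inducible
#' @export
inducibility <- function(cycle_outcomes) {
  if (!length(cycle_outcomes)) stop("empty cohort")
  if (is.logical(cycle_outcomes)) cycle_outcomes <- list(cycle_outcomes)
  if (any(!vapply(cycle_outcomes, length, integer(1))))
    stop("every animal needs at least one cycle outcome")
  per <- do.call(rbind, lapply(seq_along(cycle_outcomes), function(i) {
    o <- cycle_outcomes[[i]]
    data.frame(animal = i, n_cycles = length(o), n_induced = sum(o),
               cycle_inducibility_pct = 100 * sum(o) / length(o),
               animal_inducible = any(o))
  }))
  pct <- per$cycle_inducibility_pct
  durs <- unlist(attr(cycle_outcomes, "durations"))
  structure(list(
    per_animal = per,
    pct_animals_inducible = round(100 * mean(per$animal_inducible), 1),
    cycle_inducibility_mean = mean(pct),
    cycle_inducibility_sem = if (length(pct) > 1)
      stats::sd(pct) / sqrt(length(pct)) else NA_real_,
    induced_af_duration_mean = if (length(durs)) mean(durs) else NA_real_,
    induced_af_duration_sd = if (length(durs) > 1) stats::sd(durs) else NA_real_),
    class = "inducibility_summary")
}
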