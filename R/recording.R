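BEAT_LABELS <- c("sinus", "apb", "af", "artifact")

#' Construct an annotated recording
#'
#' The central container of the pipeline: a beat-time series with per-beat
#' rhythm labels and P-wave flags, ground-truth episode table, and an
#' optional rendered single-lead waveform.
#'
#' @param beat_times Strictly increasing beat times, seconds.
#' @param beat_labels Per-beat labels, one of sinus/apb/af/artifact.
#' @param p_present Logical per beat: a P wave precedes the QRS.
#' @param p_morph_match Logical per beat: the P morphology matches sinus.
#' @param true_episodes Data frame with columns start_s, end_s, type,
#'   n_beats (ground-truth arrhythmic episodes).
#' @param waveform Optional list with elements \code{samples} (mV) and
#'   \code{fs} (Hz).
#' @param duration Recording length, seconds.
#' @param represents_s Recording time the recording stands for, seconds
#'   (equals \code{duration} unless the recording is time-compressed).
#' @param meta Optional named list (animal id, period, arm, ...).
#' @return An object of class \code{annotated_recording}.
#' @export
annotated_recording <- function(beat_times,
                                beat_labels = rep("sinus", length(beat_times)),
                                p_present = beat_labels != "af",
                                p_morph_match = beat_labels == "sinus",
                                true_episodes = empty_episodes(),
                                waveform = NULL,
                                duration,
                                represents_s = duration,
                                meta = list()) {
  beat_times <- as.numeric(beat_times)
  n <- length(beat_times)
  if (n && any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing")
  if (length(beat_labels) != n || length(p_present) != n ||
      length(p_morph_match) != n)
    stop("label/flag arrays must match beat_times in length")
  if (n && !all(beat_labels %in% BEAT_LABELS))
    stop("beat_labels must be one of ", paste(BEAT_LABELS, collapse = ", "))
  if (any(p_present[beat_labels == "af"]))
    stop("af beats must have p_present = FALSE")
  stopifnot(is.data.frame(true_episodes), duration >= 0, represents_s > 0 || duration == 0)
  af_eps <- true_episodes[true_episodes$type == "af", , drop = FALSE]
  if (nrow(af_eps) && any(af_eps$n_beats < 3))
    stop("every ground-truth af episode must span >= 3 beats")
  rec <- structure(
    list(beat_times = beat_times,
         beat_labels = as.character(beat_labels),
         p_present = as.logical(p_present),
         p_morph_match = as.logical(p_morph_match),
         true_episodes = true_episodes,
         waveform = waveform,
         duration = as.numeric(duration),
         represents_s = as.numeric(represents_s),
         meta = meta),
    class = "annotated_recording")
  rec
}

empty_episodes <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             type = character(0), n_beats = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_recording <- function(x, ...) {
  tab <- table(factor(x$beat_labels, levels = BEAT_LABELS))
  cat(sprintf("<annotated_recording> %.1f s, %d beats (%s)\n",
              x$duration, length(x$beat_times),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  naf <- sum(x$true_episodes$type == "af")
  cat(sprintf("  ground-truth af episodes: %d; waveform: %s\n", naf,
              if (is.null(x$waveform)) "none"
              else sprintf("%d samples @ %g Hz", length(x$waveform$samples),
                           x$waveform$fs)))
  invisible(x)
}

#' RR interval series from beat times
#'
#' @param r_times Beat (R-peak) times, seconds.
#' @return Data frame with columns \code{time_s} (interval start time) and
#'   \code{rr_ms}; zero rows when fewer than two beats are supplied.
#' @examples
#' rr_series(c(0, 0.2, 0.4))
#' @export
rr_series <- function(r_times) {
  r_times <- as.numeric(r_times)
  if (length(r_times) < 2)
    return(data.frame(time_s = numeric(0), rr_ms = numeric(0)))
  data.frame(time_s = r_times[-length(r_times)],
             rr_ms = diff(r_times) * 1000)
}

# Run expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic sub-seed derivation (keeps results < 2^31).
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}
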