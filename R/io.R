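#' Write an annotated recording to a directory
#'
#' On-disk dialect: \code{beats.csv} (time_s, label, p_present,
#' p_morph_match), \code{episodes.csv} (start_s, end_s, type, n_beats),
#' optional \code{waveform.csv} (time_s, mv), and a \code{meta.json}
#' sidecar (duration, represents_s, sampling rate, metadata).
#'
#' @param rec An \code{\link{annotated_recording}}.
#' @param dir Output directory (created if needed).
#' @param waveform Also write the rendered waveform when present (large).
#' @return \code{dir}, invisibly.
#' @export
write_recording <- function(rec, dir, waveform = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    time_s = rec$beat_times, label = rec$beat_labels,
    p_present = rec$p_present, p_morph_match = rec$p_morph_match),
    file.path(dir, "beats.csv"), row.names = FALSE)
  utils::write.csv(rec$true_episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  meta <- list(duration = rec$duration, represents_s = rec$represents_s,
               meta = rec$meta,
               fs = if (!is.null(rec$waveform)) rec$waveform$fs else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (waveform && !is.null(rec$waveform)) {
    w <- rec$waveform
    utils::write.csv(data.frame(
      time_s = (seq_along(w$samples) - 1) / w$fs, mv = w$samples),
      file.path(dir, "waveform.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read an annotated recording written by \code{\link{write_recording}}
#'
#' @param dir Directory holding beats.csv / episodes.csv / meta.json.
#' @return An \code{\link{annotated_recording}}.
#' @export
read_recording <- function(dir) {
  beats <- utils::read.csv(file.path(dir, "beats.csv"),
                           stringsAsFactors = FALSE)
  eps <- utils::read.csv(file.path(dir, "episodes.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(start_s = "numeric",
                                        end_s = "numeric",
                                        type = "character",
                                        n_beats = "integer"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  wf <- NULL
  wpath <- file.path(dir, "waveform.csv")
  if (file.exists(wpath) && !is.null(meta$fs)) {
    w <- utils::read.csv(wpath)
    wf <- list(samples = w$mv, fs = meta$fs, noise_sd = NA_real_)
  }
  annotated_recording(
    beat_times = beats$time_s, beat_labels = beats$label,
    p_present = beats$p_present, p_morph_match = beats$p_morph_match,
    true_episodes = eps, waveform = wf,
    duration = meta$duration, represents_s = meta$represents_s,
    meta = as.list(meta$meta))
}

#' Write a cohort with manifest
#'
#' One subdirectory per recording plus \code{manifest.json} listing
#' (animal, arm, period, path).
#'
#' @param recs Cohort list from \code{\link{generate_cohort}}.
#' @param dir Output directory.
#' @param waveform Include waveform CSVs.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(recs, dir, waveform = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- attr(recs, "index")
  idx$path <- idx$name
  for (i in seq_len(nrow(idx)))
    write_recording(recs[[idx$name[i]]], file.path(dir, idx$path[i]),
                    waveform = waveform)
  jsonlite::write_json(idx, file.path(dir, "manifest.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir Cohort directory with manifest.json.
#' @return Named recording list with \code{"index"} attribute.
#' @export
read_cohort <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  recs <- lapply(idx$path, function(p) read_recording(file.path(dir, p)))
  names(recs) <- idx$name
  attr(recs, "index") <- idx[, c("animal", "arm", "period", "name")]
  recs
}
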