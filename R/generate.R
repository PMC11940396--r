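#' Generate sinus beat times by integral pulse frequency modulation
#'
#' The instantaneous beat rate is
#' \deqn{m(t) = (\mathrm{HR}/60)\,[1 + d_{LF}\sin(2\pi f_{LF} t + \phi_1)
#'              + d_{HF}\sin(2\pi f_{HF} t + \phi_2)]}
#' and a beat is emitted each time \eqn{\int_0^t m\,du} crosses an integer
#' (IPFM). Multiplicative white lognormal jitter with coefficient of
#' variation \code{rr_jitter_cv} is then applied to each RR interval.
#' Modulation phases are drawn uniformly from the seed.
#'
#' @param params An \code{\link{autonomic_params}} object.
#' @param duration Recording length, seconds (>= 0).
#' @param seed Integer seed; output is a pure function of params and seed.
#' @return Numeric vector of strictly increasing beat times in (0, duration].
#' @examples
#' # unmodulated, jitter-free: metronomic rhythm at exactly mean_hr
#' t <- generate_nn_times(autonomic_params(300, 0, 0, rr_jitter_cv = 0), 60, 1)
#' length(t)            # 300 beats
#' unique(diff(t))      # all RR = 0.2 s
#' @export
generate_nn_times <- function(params, duration, seed = 1L) {
  stopifnot(inherits(params, "autonomic_params"))
  if (!is.finite(duration) || duration < 0)
    stop("duration must be finite and >= 0")
  if (duration == 0) return(numeric(0))
  if (params$lf_mod_depth + params$hf_mod_depth >= 1)
    stop("summed modulation depths must stay below 1 (rate must stay positive)")
  r0 <- params$mean_hr / 60
  a1 <- params$lf_mod_depth; f1 <- params$lf_freq
  a2 <- params$hf_mod_depth; f2 <- params$hf_freq
  with_seed(seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    # closed-form integral of m(t); M(0) = 0, strictly increasing
    M <- function(t) {
      out <- t
      if (a1 > 0)
        out <- out - a1 / (2 * pi * f1) * (cos(2 * pi * f1 * t + ph[1]) - cos(ph[1]))
      if (a2 > 0)
        out <- out - a2 / (2 * pi * f2) * (cos(2 * pi * f2 * t + ph[2]) - cos(ph[2]))
      r0 * out
    }
    n_beats <- floor(M(duration) + 1e-9)
    if (n_beats < 1) return(numeric(0))
    if (a1 == 0 && a2 == 0) {
      times <- (1:n_beats) / r0
    } else {
      # invert M on a fine grid; M is smooth so linear interpolation at
      # 2 ms resolution is far below beat-timing precision of interest
      grid <- seq(0, duration, by = 0.002)
      if (grid[length(grid)] < duration) grid <- c(grid, duration)
      times <- stats::approx(M(grid), grid, xout = 1:n_beats, ties = "ordered")$y
    }
    cv <- params$rr_jitter_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      jit <- stats::rlnorm(n_beats, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rr <- diff(c(0, times)) * jit
      times <- cumsum(rr)
      times <- times[times <= duration + 1e-9]
    }
    times
  })
}

#' Inject atrial premature beats into a recording
#'
#' The number of APBs is Poisson with mean \code{apb_rate} (events/hour)
#' times the represented recording time. Each APB advances an existing
#' sinus beat to a coupling interval of \code{apb_prematurity} times the
#' preceding sinus RR; the following beat keeps its original time, i.e.
#' a full (non-resetting) compensatory pause, so no downstream sinus beat
#' moves. APBs carry a P wave of altered morphology
#' (\code{p_morph_match = FALSE}).
#'
#' @param rec An \code{\link{annotated_recording}} with >= 2 sinus beats.
#' @param params An \code{\link{arrhythmia_params}} object.
#' @param seed Integer seed.
#' @return The modified recording.
#' @export
inject_apbs <- function(rec, params, seed = 1L) {
  stopifnot(inherits(rec, "annotated_recording"),
            inherits(params, "arrhythmia_params"))
  if (sum(rec$beat_labels == "sinus") < 2)
    stop("recording must contain at least 2 sinus beats")
  if (params$apb_rate == 0) return(rec)
  with_seed(seed, {
    n_target <- stats::rpois(1, params$apb_rate * rec$represents_s / 3600)
    if (n_target == 0) return(rec)
    n <- length(rec$beat_times)
    sinus <- rec$beat_labels == "sinus"
    # candidate beats: sinus with sinus neighbours on both sides, interior
    cand <- which(sinus & c(FALSE, sinus[-n]) & c(sinus[-1], FALSE))
    cand <- setdiff(cand, c(1L, n))
    if (!length(cand)) return(rec)
    pick <- sort(sample(cand, min(n_target, length(cand))))
    # forbid adjacent picks so each APB's preceding beat stays sinus
    keep <- c(TRUE, diff(pick) > 1)
    pick <- pick[keep]
    t <- rec$beat_times
    t[pick] <- t[pick - 1] + params$apb_prematurity * (t[pick] - t[pick - 1])
    rec$beat_times <- t
    rec$beat_labels[pick] <- "apb"
    rec$p_morph_match[pick] <- FALSE
    rec
  })
}

#' Inject atrial fibrillation episodes into a recording
#'
#' Episode onsets are Poisson with mean \code{af_rate} (episodes/24 h of
#' represented time); durations are lognormal with the given mean and SD.
#' In a time-compressed recording (\code{represents_s > duration}) the
#' placed durations are scaled by \code{duration / represents_s} so the
#' fraction of recording time spent in AF matches the represented day;
#' \code{\link{burden_24h}} converts episode durations back to the
#' represented scale.
#' Within an episode, sinus beats are replaced by a rapid irregular beat
#' train: RR = \code{af_rr_scale} times the local sinus RR with lognormal
#' coefficient of variation \code{af_rr_cv}, all beats labeled \code{af}
#' with absent P waves. Episodes shorter than three beats are extended to
#' three. Ground truth is appended to \code{true_episodes} using the study
#' convention: an episode runs from its first arrhythmic beat to the first
#' subsequent sinus beat.
#'
#' @inheritParams inject_apbs
#' @return The modified recording.
#' @export
inject_af_episodes <- function(rec, params, seed = 1L) {
  stopifnot(inherits(rec, "annotated_recording"),
            inherits(params, "arrhythmia_params"))
  if (params$af_rate == 0) return(rec)
  if (params$af_duration_mean <= 0)
    stop("af_duration_mean must be > 0 when af_rate > 0")
  with_seed(seed, {
    n_ep <- stats::rpois(1, params$af_rate * rec$represents_s / 86400)
    if (n_ep == 0) return(rec)
    m <- params$af_duration_mean; s <- params$af_duration_sd
    sdlog <- sqrt(log(1 + (s / m)^2))
    durs <- stats::rlnorm(n_ep, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    durs <- durs * rec$duration / rec$represents_s
    skipped <- 0L
    for (dur in durs) {
      res <- af_splice(rec, dur, params)
      if (is.null(res)) skipped <- skipped + 1L else rec <- res
    }
    if (skipped > 0)
      warning(skipped, " AF episode(s) could not be placed in a free sinus ",
              "segment and were skipped")
    rec
  })
}

# Splice one AF episode of target duration `dur` into a sinus stretch.
# Uses the ambient RNG stream (callers wrap in with_seed). Returns NULL
# when no free all-sinus window can be found.
af_splice <- function(rec, dur, params) {
  t <- rec$beat_times
  n <- length(t)
  margin <- 2
  lo <- margin; hi <- rec$duration - dur - margin
  if (hi <= lo) return(NULL)
  # find an all-sinus window, avoiding overlap with existing episodes
  placed <- FALSE
  for (attempt in 1:50) {
    t0 <- stats::runif(1, lo, hi)
    idx <- which(t >= t0 & t <= t0 + dur + margin)
    if (length(idx) >= 2 && all(rec$beat_labels[idx] == "sinus") &&
        idx[length(idx)] < n) { placed <- TRUE; break }
  }
  if (!placed) return(NULL)
  first <- idx[1]
  # local sinus RR: median of the last 11 intervals bounded by sinus
  # beats and ending before the episode onset -- the same reference
  # window the rhythm classifier uses, so the programmed rapidity
  # (af_rr_scale x local RR) is preserved under analysis
  sin_b <- rec$beat_labels == "sinus"
  k <- which(sin_b[-n] & sin_b[-1])        # interval k bounded by sinus
  k <- k[k <= first - 2L]
  rr_local <- if (length(k) >= 3)
    stats::median(utils::tail(diff(t)[utils::tail(k, 11)], 11))
  else if (first > 1) t[first] - t[first - 1]
  else t[2] - t[1]
  t_start <- t[first]
  # rapid irregular beat train
  sdlog <- sqrt(log(1 + params$af_rr_cv^2))
  mu <- log(params$af_rr_scale * rr_local) - sdlog^2 / 2
  af_times <- t_start
  repeat {
    nt <- af_times[length(af_times)] + stats::rlnorm(1, mu, sdlog)
    if (nt - t_start >= dur && length(af_times) >= 3) break
    af_times <- c(af_times, nt)
  }
  t_last <- af_times[length(af_times)]
  # drop original beats covered by the episode plus a recovery interval
  drop <- which(t >= t_start & t <= t_last + 0.5 * rr_local)
  keep_before <- seq_len(drop[1] - 1)
  keep_after <- if (drop[length(drop)] < n) (drop[length(drop)] + 1):n else integer(0)
  if (!length(keep_after)) return(NULL)
  n_af <- length(af_times)
  rec$beat_times <- c(t[keep_before], af_times, t[keep_after])
  rec$beat_labels <- c(rec$beat_labels[keep_before], rep("af", n_af),
                       rec$beat_labels[keep_after])
  rec$p_present <- c(rec$p_present[keep_before], rep(FALSE, n_af),
                     rec$p_present[keep_after])
  rec$p_morph_match <- c(rec$p_morph_match[keep_before], rep(FALSE, n_af),
                         rec$p_morph_match[keep_after])
  end_s <- rec$beat_times[length(keep_before) + n_af + 1]
  ep <- data.frame(start_s = t_start, end_s = end_s, type = "af",
                   n_beats = n_af, stringsAsFactors = FALSE)
  rec$true_episodes <- rbind(rec$true_episodes, ep)
  rec$true_episodes <- rec$true_episodes[order(rec$true_episodes$start_s), ,
                                         drop = FALSE]
  rec
}
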