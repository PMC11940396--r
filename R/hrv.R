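#' HRV configuration with rat spectral bands
#'
#' @param lf_band,hf_band Band edges, Hz. Rat defaults: LF 0.3-0.6 Hz,
#'   HF 0.6-2.5 Hz.
#' @param pnn_threshold Successive-difference threshold for pNN, ms
#'   (rodent-scaled pNN5 by default; comparison is strict \code{>}).
#' @param epoch_length Analysis epoch, seconds.
#' @param min_nn_fraction Minimum fraction of expected NN intervals for an
#'   epoch to count as valid.
#' @param exclusion_margin Intervals dropped on each side of a non-normal
#'   interval.
#' @param spectral_method \code{"lomb"} (Lomb-Scargle on the native uneven
#'   time base; default) or \code{"interp_fft"} (4 Hz cubic resampling +
#'   FFT periodogram, for comparison).
#' @return An object of class \code{hrv_config}.
#' @export
hrv_config <- function(lf_band = c(0.3, 0.6),
                       hf_band = c(0.6, 2.5),
                       pnn_threshold = 5,
                       epoch_length = 300,
                       min_nn_fraction = 0.8,
                       exclusion_margin = 1,
                       spectral_method = c("lomb", "interp_fft")) {
  stopifnot(length(lf_band) == 2, length(hf_band) == 2,
            all(c(lf_band, hf_band) > 0),
            lf_band[2] > lf_band[1], hf_band[2] > hf_band[1],
            pnn_threshold > 0, epoch_length > 0,
            min_nn_fraction > 0, min_nn_fraction <= 1,
            exclusion_margin >= 0)
  structure(list(lf_band = lf_band, hf_band = hf_band,
                 pnn_threshold = pnn_threshold, epoch_length = epoch_length,
                 min_nn_fraction = min_nn_fraction,
                 exclusion_margin = exclusion_margin,
                 spectral_method = match.arg(spectral_method)),
            class = "hrv_config")
}

#' Exclude arrhythmic and artifact intervals from an RR series
#'
#' An interval inherits the worst label of its two bounding beats; every
#' interval touching a non-sinus beat is dropped together with
#' \code{exclusion_margin} neighbours on each side. Original timestamps
#' are retained (no gap splicing), as the spectral estimator works on the
#' native uneven time base.
#'
#' @param rr Data frame from \code{\link{rr_series}} (time_s, rr_ms), or a
#'   numeric vector of RR ms with a \code{times} argument implied by
#'   cumulative sums.
#' @param labels Per-beat labels, length \code{nrow(rr) + 1}.
#' @param cfg An \code{\link{hrv_config}}.
#' @return The NN subset of \code{rr} (same columns).
#' @export
exclude_non_normal <- function(rr, labels, cfg = hrv_config()) {
  if (!is.data.frame(rr))
    rr <- data.frame(time_s = cumsum(c(0, rr[-length(rr)])) / 1000, rr_ms = rr)
  n_int <- nrow(rr)
  if (length(labels) != n_int + 1)
    stop("labels must align with beats (intervals + 1)")
  bad_beat <- labels != "sinus"
  bad_int <- bad_beat[-length(bad_beat)] | bad_beat[-1]
  if (cfg$exclusion_margin > 0 && any(bad_int)) {
    idx <- which(bad_int)
    for (m in seq_len(cfg$exclusion_margin))
      bad_int[pmin(pmax(c(idx - m, idx + m), 1L), n_int)] <- TRUE
  }
  rr[!bad_int, , drop = FALSE]
}

#' Time-domain HRV metrics
#'
#' SDNN is the n-1-denominator standard deviation of NN intervals; RMSSD
#' the root mean square of successive NN differences; pNN the percentage
#' of successive differences strictly exceeding \code{pnn_threshold}
#' (5 ms for rat pNN5).
#'
#' @param nn NN intervals, ms (vector or data frame with \code{rr_ms}).
#' @param cfg An \code{\link{hrv_config}}.
#' @return List of class \code{hrv_time}: sdnn (ms), rmssd (ms), pnn (%),
#'   n. Metrics that cannot be computed are \code{NA} (flagged, never
#'   zero-filled).
#' @examples
#' time_domain(rep(c(160, 170), 10))  # rmssd = 10 ms, pnn5 = 100%
#' @export
time_domain <- function(nn, cfg = hrv_config()) {
  if (is.data.frame(nn)) nn <- nn$rr_ms
  n <- length(nn)
  sdnn <- if (n >= 2) stats::sd(nn) else NA_real_
  if (n >= 3) {
    d <- diff(nn)
    rmssd <- sqrt(mean(d^2))
    pnn <- 100 * sum(abs(d) > cfg$pnn_threshold) / length(d)
  } else {
    rmssd <- NA_real_; pnn <- NA_real_
  }
  structure(list(sdnn = sdnn, rmssd = rmssd, pnn = pnn, n = n),
            class = "hrv_time")
}

# Lomb-Scargle periodogram of (t, x) at frequencies f (Hz), normalized so
# that sum(psd * df) over the standard grid recovers the series variance
# (Parseval-style) for an evenly sampled series.
lomb_psd <- function(t, x, f) {
  x <- x - mean(x)
  n <- length(x)
  psd <- vapply(f, function(fi) {
    w <- 2 * pi * fi
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    p <- 0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    p
  }, numeric(1))
  span <- max(t) - min(t)
  # classic power -> PSD: 2 P / (n df) with df = 1/span
  2 * psd * span / n
}

#' Frequency-domain HRV on the native uneven time base
#'
#' Estimates the NN power spectral density with a variance-preserving
#' Lomb-Scargle periodogram evaluated on the standard frequency grid
#' (spacing 1/span up to the pseudo-Nyquist rate, half the mean beat
#' rate), then integrates the rat LF and HF bands. An evenly resampled
#' FFT path is available via \code{cfg$spectral_method = "interp_fft"}.
#'
#' @param nn NN intervals, ms.
#' @param nn_times Interval timestamps, s (aligned with \code{nn}).
#' @param cfg An \code{\link{hrv_config}}.
#' @return List of class \code{hrv_freq}: lf (ms^2), hf (ms^2), lf_hf,
#'   total_power (ms^2), and the psd grid (data frame freq_hz, psd).
#'   \code{lf_hf} is \code{NA} when HF power is zero.
#' @export
frequency_domain <- function(nn, nn_times, cfg = hrv_config()) {
  if (is.data.frame(nn)) {
    nn_times <- nn$time_s; nn <- nn$rr_ms
  }
  if (length(nn) < 64) stop("need >= 64 NN intervals for spectral analysis")
  span <- max(nn_times) - min(nn_times)
  if (span < 30) stop("NN series must span >= 30 s")
  mean_rate <- length(nn) / span
  fmax <- min(mean_rate / 2, cfg$hf_band[2] * 1.2)
  df <- 1 / span
  f <- seq(df, fmax, by = df)
  if (cfg$spectral_method == "lomb") {
    psd <- lomb_psd(nn_times, nn, f)
  } else {
    fs_r <- 4 * cfg$hf_band[2]
    tg <- seq(min(nn_times), max(nn_times), by = 1 / fs_r)
    xg <- stats::spline(nn_times, nn, xout = tg)$y
    xg <- xg - mean(xg)
    per <- Mod(stats::fft(xg))^2 / length(xg)^2
    fg <- (seq_along(xg) - 1) / length(xg) * fs_r
    psd <- 2 * stats::approx(fg[seq_len(floor(length(xg) / 2))],
                             per[seq_len(floor(length(xg) / 2))] / (fg[2] - fg[1]),
                             xout = f, rule = 2)$y
  }
  band_power <- function(band)
    sum(psd[f >= band[1] & f < band[2]]) * df
  lf <- band_power(cfg$lf_band)
  hf <- band_power(cfg$hf_band)
  structure(list(lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_,
                 total_power = sum(psd) * df,
                 psd = data.frame(freq_hz = f, psd = psd)),
            class = "hrv_freq")
}

#' Epoch-wise HRV for a whole recording, aggregated by medians
#'
#' Splits the NN series into epochs of \code{epoch_length} seconds,
#' computes time- and frequency-domain metrics per epoch, rejects epochs
#' with fewer than \code{min_nn_fraction} of the expected NN count, and
#' reports the per-metric median across valid epochs.
#'
#' @param nn Data frame (time_s, rr_ms) of NN intervals, e.g. from
#'   \code{\link{exclude_non_normal}}.
#' @param cfg An \code{\link{hrv_config}}.
#' @param freq Also compute frequency-domain metrics per epoch (slower).
#' @return List of class \code{hrv_summary}: sdnn, rmssd, pnn, and (when
#'   \code{freq}) lf, hf, lf_hf; plus n_epochs, n_valid, n_rejected and
#'   the per-epoch table. All-\code{NA} metrics when no epoch is valid.
#' @export
aggregate_recording <- function(nn, cfg = hrv_config(), freq = TRUE) {
  stopifnot(is.data.frame(nn))
  if (!nrow(nn)) {
    return(structure(list(sdnn = NA_real_, rmssd = NA_real_, pnn = NA_real_,
                          lf = NA_real_, hf = NA_real_, lf_hf = NA_real_,
                          n_epochs = 0L, n_valid = 0L, n_rejected = 0L,
                          epochs = NULL), class = "hrv_summary"))
  }
  t0 <- min(nn$time_s)
  ep_id <- floor((nn$time_s - t0) / cfg$epoch_length)
  med_rr <- stats::median(nn$rr_ms)
  expected <- cfg$epoch_length / (med_rr / 1000)
  rows <- list()
  for (e in sort(unique(ep_id))) {
    sub <- nn[ep_id == e, , drop = FALSE]
    valid <- nrow(sub) >= cfg$min_nn_fraction * expected
    td <- time_domain(sub$rr_ms, cfg)
    fd <- NULL
    if (freq && valid && nrow(sub) >= 64 &&
        diff(range(sub$time_s)) >= 30)
      fd <- frequency_domain(sub$rr_ms, sub$time_s, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      epoch = e, n = nrow(sub), valid = valid,
      sdnn = td$sdnn, rmssd = td$rmssd, pnn = td$pnn,
      lf = if (is.null(fd)) NA_real_ else fd$lf,
      hf = if (is.null(fd)) NA_real_ else fd$hf,
      lf_hf = if (is.null(fd)) NA_real_ else fd$lf_hf)
  }
  ep <- do.call(rbind, rows)
  val <- ep[ep$valid, , drop = FALSE]
  med <- function(v) if (nrow(val) && any(is.finite(v[ep$valid])))
    stats::median(v[ep$valid], na.rm = TRUE) else NA_real_
  structure(list(sdnn = med(ep$sdnn), rmssd = med(ep$rmssd), pnn = med(ep$pnn),
                 lf = med(ep$lf), hf = med(ep$hf), lf_hf = med(ep$lf_hf),
                 n_epochs = nrow(ep), n_valid = nrow(val),
                 n_rejected = nrow(ep) - nrow(val), epochs = ep),
            class = "hrv_summary")
}
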