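# Beat morphology templates for a rat lead-II ECG, seconds/mV.
# Narrow QRS (~15 ms), small P (~0.1 mV) ending ~25 ms before the R peak,
# modest T. APBs carry a biphasic "ectopic" P that correlates only
# partially with the sinus P; AF beats carry no P at all.
ecg_template <- function(offsets, label = "sinus") {
  g <- function(mu, sigma, amp) amp * exp(-(offsets - mu)^2 / (2 * sigma^2))
  v <- g(0, 0.0035, 1.0) +          # R
    g(-0.008, 0.002, -0.10) +       # Q
    g(0.008, 0.002, -0.20) +        # S
    g(0.030, 0.008, 0.12)           # T (rat T is short, merges into QRS)
  if (label == "sinus") v <- v + g(-0.045, 0.006, 0.10)
  if (label == "apb") v <- v + g(-0.040, 0.006, -0.10)  # inverted ectopic P
  v
}

#' Render an annotated beat train as a single-lead ECG waveform
#'
#' Each beat contributes P + QRS + T templates centred on its beat time;
#' AF beats omit the P wave entirely, APB beats use an altered (biphasic)
#' P. Additive white Gaussian noise is applied last. The rendered trace is
#' attached to the recording as \code{waveform = list(samples, fs, noise_sd)}.
#'
#' @param rec An \code{\link{annotated_recording}}.
#' @param fs Sampling rate, Hz; at least 500 (a rat QRS spans ~15 ms).
#' @param noise_sd Additive Gaussian noise SD, mV.
#' @param seed Integer seed for the noise.
#' @return The recording with \code{$waveform} set.
#' @export
render_ecg <- function(rec, fs = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(rec, "annotated_recording"))
  if (!is.finite(fs) || fs < 500)
    stop("fs must be >= 500 Hz: a rat QRS is unresolvable below that")
  n <- ceiling(rec$duration * fs) + 1L
  x <- numeric(n)
  half <- round(0.085 * fs)   # template support: [-85, +85] ms
  for (i in seq_along(rec$beat_times)) {
    c_idx <- round(rec$beat_times[i] * fs) + 1L
    lo <- max(1L, c_idx - half); hi <- min(n, c_idx + half)
    if (lo > hi) next
    offs <- ((lo:hi) - 1L) / fs - rec$beat_times[i]
    x[lo:hi] <- x[lo:hi] + ecg_template(offs, rec$beat_labels[i])
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  rec$waveform <- list(samples = x, fs = fs, noise_sd = noise_sd)
  rec
}

#' Noise level giving a target signal-to-noise ratio
#'
#' @param rec A recording already rendered (or rendered on the fly) noise
#'   free; SNR is defined against the RMS of the noise-free trace.
#' @param snr_db Target SNR in dB.
#' @param fs Sampling rate used for the reference render.
#' @return Noise SD in mV.
#' @export
noise_sd_for_snr <- function(rec, snr_db, fs = 1000) {
  clean <- if (!is.null(rec$waveform) && rec$waveform$noise_sd == 0)
    rec$waveform$samples
  else render_ecg(rec, fs = fs, noise_sd = 0)$waveform$samples
  sqrt(mean(clean^2)) / 10^(snr_db / 20)
}
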