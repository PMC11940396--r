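#' Autonomic modulation parameters for the beat-train generator
#'
#' Describes rat sinus rhythm as a mean heart rate plus sinusoidal
#' low-frequency (LF) and high-frequency (HF) rate modulation and white
#' multiplicative RR jitter. The LF and HF carrier frequencies must sit
#' inside the rat spectral bands (LF 0.3-0.6 Hz, HF 0.6-2.5 Hz).
#'
#' @param mean_hr Mean heart rate, beats/min. Rat sinus rhythm is typically
#'   310-345 bpm.
#' @param lf_mod_depth Fractional depth of LF rate modulation (0 <= d < 1).
#' @param hf_mod_depth Fractional depth of HF rate modulation (0 <= d < 1).
#' @param lf_freq LF carrier frequency, Hz; must lie in [0.3, 0.6].
#' @param hf_freq HF carrier frequency, Hz; must lie in [0.6, 2.5].
#' @param rr_jitter_cv Coefficient of variation of white multiplicative RR
#'   jitter (dimensionless).
#' @return An object of class \code{autonomic_params}.
#' @examples
#' autonomic_params(mean_hr = 344.7)
#' @export
autonomic_params <- function(mean_hr = 344.7,
                             lf_mod_depth = 0.042,
                             hf_mod_depth = 0.085,
                             lf_freq = 0.45,
                             hf_freq = 1.5,
                             rr_jitter_cv = 0.10) {
  stopifnot(is.numeric(mean_hr), length(mean_hr) == 1L)
  if (!is.finite(mean_hr) || mean_hr <= 0)
    stop("mean_hr must be a positive finite number (beats/min)")
  for (d in c(lf_mod_depth, hf_mod_depth)) {
    if (!is.finite(d) || d < 0 || d >= 1)
      stop("modulation depths must be finite and in [0, 1)")
  }
  if (!is.finite(lf_freq) || lf_freq < 0.3 || lf_freq > 0.6)
    stop("lf_freq must lie inside the rat LF band [0.3, 0.6] Hz")
  if (!is.finite(hf_freq) || hf_freq < 0.6 || hf_freq > 2.5)
    stop("hf_freq must lie inside the rat HF band [0.6, 2.5] Hz")
  if (!is.finite(rr_jitter_cv) || rr_jitter_cv < 0)
    stop("rr_jitter_cv must be finite and >= 0")
  structure(
    list(mean_hr = mean_hr, lf_mod_depth = lf_mod_depth,
         hf_mod_depth = hf_mod_depth, lf_freq = lf_freq, hf_freq = hf_freq,
         rr_jitter_cv = rr_jitter_cv),
    class = "autonomic_params")
}

#' Arrhythmia injection parameters
#'
#' Rates are expressed against represented recording time (APBs per hour,
#' AF episodes per 24 h). Desk-scale compression -- a short recording that
#' stands for a full day -- is declared on the \code{\link{period_spec}}
#' via \code{represents_s}, so rates keep their natural units.
#'
#' @param apb_rate Atrial premature beats per hour of represented time.
#' @param apb_prematurity Coupling interval of an APB as a fraction of the
#'   preceding sinus RR, in (0, 1).
#' @param af_rate Spontaneous AF episodes per 24 h of represented time.
#' @param af_duration_mean,af_duration_sd Mean and SD of episode duration,
#'   seconds. Defaults follow the induced-episode durations reported for
#'   this model (123.2 +/- 36.4 s).
#' @param af_rr_scale RR during AF as a fraction of the local sinus RR.
#' @param af_rr_cv Coefficient of variation of RR within an AF episode
#'   (the "irregular" part of rapid, irregular rhythm).
#' @return An object of class \code{arrhythmia_params}.
#' @export
arrhythmia_params <- function(apb_rate = 0,
                              apb_prematurity = 0.6,
                              af_rate = 0,
                              af_duration_mean = 123.2,
                              af_duration_sd = 36.4,
                              af_rr_scale = 0.7,
                              af_rr_cv = 0.15) {
  if (any(!is.finite(c(apb_rate, af_rate))) || apb_rate < 0 || af_rate < 0)
    stop("arrhythmia rates must be finite and >= 0")
  if (!is.finite(apb_prematurity) || apb_prematurity <= 0 || apb_prematurity >= 1)
    stop("apb_prematurity must lie in (0, 1)")
  if (af_rate > 0 && (!is.finite(af_duration_mean) || af_duration_mean <= 0))
    stop("af_duration_mean must be > 0 when af_rate > 0")
  if (!is.finite(af_rr_scale) || af_rr_scale <= 0 || af_rr_scale >= 1)
    stop("af_rr_scale must lie in (0, 1)")
  if (!is.finite(af_rr_cv) || af_rr_cv <= 0)
    stop("af_rr_cv must be > 0")
  if (af_duration_sd < 0) stop("af_duration_sd must be >= 0")
  structure(
    list(apb_rate = apb_rate, apb_prematurity = apb_prematurity,
         af_rate = af_rate, af_duration_mean = af_duration_mean,
         af_duration_sd = af_duration_sd, af_rr_scale = af_rr_scale,
         af_rr_cv = af_rr_cv),
    class = "arrhythmia_params")
}

#' Transesophageal atrial burst-pacing protocol
#'
#' Bookkeeping for the daily pacing schedule: defaults are 15 successive
#' 20-s stimulation cycles separated by 5-min free intervals, at
#' 4000 stimuli/min with 6-ms stimuli, repeated for 10 days.
#'
#' @param cycles_per_day Number of stimulation cycles per day.
#' @param cycle_duration Cycle length, seconds.
#' @param inter_cycle_interval Free interval between cycles, seconds.
#' @param stim_rate Stimulation rate, stimuli/min.
#' @param stim_duration Single-stimulus duration, ms.
#' @param n_days Protocol length, days.
#' @param per_cycle_induction_prob Probability that a cycle is followed by
#'   an induced AF episode (used when simulating inducibility outcomes).
#' @return An object of class \code{stimulation_protocol}.
#' @export
stimulation_protocol <- function(cycles_per_day = 15,
                                 cycle_duration = 20,
                                 inter_cycle_interval = 300,
                                 stim_rate = 4000,
                                 stim_duration = 6,
                                 n_days = 10,
                                 per_cycle_induction_prob = 0.44) {
  stopifnot(cycles_per_day >= 1, cycle_duration > 0,
            inter_cycle_interval >= 0, stim_rate > 0, stim_duration > 0,
            n_days >= 1)
  if (!is.finite(per_cycle_induction_prob) ||
      per_cycle_induction_prob < 0 || per_cycle_induction_prob > 1)
    stop("per_cycle_induction_prob must lie in [0, 1]")
  structure(
    list(cycles_per_day = cycles_per_day, cycle_duration = cycle_duration,
         inter_cycle_interval = inter_cycle_interval, stim_rate = stim_rate,
         stim_duration = stim_duration, n_days = n_days,
         per_cycle_induction_prob = per_cycle_induction_prob),
    class = "stimulation_protocol")
}

PERIOD_LABELS <- c("before", "week1", "week2", "after")

#' One ECG monitoring period of the study design
#'
#' The study records continuous telemetry ECG in four key periods: before
#' pacing, at the end of pacing weeks 1 and 2, and one week after the end
#' of the protocol.
#'
#' @param label One of \code{"before"}, \code{"week1"}, \code{"week2"},
#'   \code{"after"}.
#' @param autonomic An \code{\link{autonomic_params}} object.
#' @param arrhythmia An \code{\link{arrhythmia_params}} object.
#' @param recording_duration Generated recording length, seconds.
#' @param represents_s Recording time the period stands for, seconds
#'   (86400 for a full day); per-24h rates and burdens are normalized
#'   against this value.
#' @return An object of class \code{period_spec}.
#' @export
period_spec <- function(label, autonomic, arrhythmia,
                        recording_duration = 3600,
                        represents_s = recording_duration) {
  label <- match.arg(label, PERIOD_LABELS)
  stopifnot(inherits(autonomic, "autonomic_params"),
            inherits(arrhythmia, "arrhythmia_params"),
            recording_duration > 0, represents_s > 0)
  structure(
    list(label = label, autonomic = autonomic, arrhythmia = arrhythmia,
         recording_duration = recording_duration,
         represents_s = represents_s),
    class = "period_spec")
}

#' Cohort specification
#'
#' @param n_control,n_af Group sizes (study defaults: 5 control, 7 AF).
#' @param periods_control,periods_af Named lists of four
#'   \code{\link{period_spec}} objects (labels before/week1/week2/after).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_control = 5, n_af = 7,
                        periods_control = default_period_specs("control"),
                        periods_af = default_period_specs("af"),
                        seed = 1L) {
  stopifnot(n_control >= 0, n_af >= 0)
  check_periods <- function(p, arm) {
    labs <- unname(vapply(p, function(x) x$label, character(1)))
    if (!identical(sort(labs), sort(PERIOD_LABELS)))
      stop("periods_", arm, " must cover exactly the four monitoring periods")
    ok <- vapply(p, inherits, logical(1), what = "period_spec")
    if (!all(ok)) stop("periods_", arm, " must be period_spec objects")
    p[order(match(labs, PERIOD_LABELS))]
  }
  periods_control <- check_periods(periods_control, "control")
  periods_af <- check_periods(periods_af, "af")
  structure(
    list(n_control = as.integer(n_control), n_af = as.integer(n_af),
         periods_control = periods_control, periods_af = periods_af,
         seed = as.integer(seed)),
    class = "cohort_spec")
}
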