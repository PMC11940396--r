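#' Default per-period simulation parameters for each study arm
#'
#' Encodes the programmed between-period trends of the study design.
#' The AF (paced) arm: mean 24-h heart rate declines across the four
#' monitoring periods (344.7, 330.6, 320.4, 318.0 bpm), overall RR
#' variability (hence SDNN) rises, the APB rate rises, and spontaneous AF
#' appears from week 1 onward. The control arm is flat, with no AF in any
#' period. Recordings are desk-scale by default: 3600 s standing for a
#' full 24 h (\code{represents_s = 86400}), so per-24h rates keep their
#' natural units and burdens normalize correctly.
#'
#' @param arm \code{"control"} or \code{"af"}.
#' @param recording_duration Generated seconds per recording.
#' @param represents_s Time the recording stands for (default one day).
#' @return Named list of four \code{\link{period_spec}} objects.
#' @export
default_period_specs <- function(arm = c("control", "af"),
                                 recording_duration = 3600,
                                 represents_s = 86400) {
  arm <- match.arg(arm)
  if (arm == "af") {
    hr <- c(before = 344.7, week1 = 330.6, week2 = 320.4, after = 318.0)
    # variability scale follows the reported AF-arm SDNN trajectory
    # (20.69, 21.37, 23.11, 26.07 ms), normalized to the first period
    vscale <- c(20.69, 21.37, 23.11, 26.07) / 20.69
    apb_rate <- c(0.5, 2, 3, 4)          # APBs/hour, rising
    af_rate <- c(0, 3, 6, 8)             # episodes/24 h, 0 before pacing
  } else {
    hr <- c(before = 320, week1 = 320, week2 = 320, after = 320)
    vscale <- rep(1, 4)
    apb_rate <- rep(0.5, 4)
    af_rate <- rep(0, 4)
  }
  specs <- lapply(seq_along(PERIOD_LABELS), function(i) {
    base <- autonomic_params()
    period_spec(
      label = PERIOD_LABELS[i],
      autonomic = autonomic_params(
        mean_hr = hr[[i]],
        lf_mod_depth = base$lf_mod_depth * vscale[i],
        hf_mod_depth = base$hf_mod_depth * vscale[i],
        rr_jitter_cv = base$rr_jitter_cv * vscale[i]),
      arrhythmia = arrhythmia_params(apb_rate = apb_rate[i],
                                     af_rate = af_rate[i]),
      recording_duration = recording_duration,
      represents_s = represents_s)
  })
  names(specs) <- PERIOD_LABELS
  specs
}

#' Generate a full annotated cohort
#'
#' Simulates every (animal, period) recording of a two-arm telemetry study.
#' Per-animal physiology is drawn once per animal (a heart-rate offset and
#' a variability multiplier, plus animal-level arrhythmia-rate multipliers)
#' and applied across all four periods, so between-period contrasts behave
#' like repeated measures on the same animal. Fully reproducible from
#' \code{spec$seed}.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param hr_animal_sd Between-animal SD of mean heart rate, bpm.
#' @param hr_period_sd Within-animal between-period HR noise, bpm.
#' @param var_animal_sdlog Between-animal lognormal SD of the variability
#'   multiplier (scales modulation depths and RR jitter).
#' @param var_period_sdlog Within-animal between-period lognormal SD of the
#'   variability multiplier.
#' @param rate_animal_sdlog Between-animal lognormal SD of APB/AF rate
#'   multipliers.
#' @return A list of \code{\link{annotated_recording}} objects named
#'   \code{"<animal>.<period>"}, with an attribute \code{"index"} holding a
#'   data frame (animal, arm, period, name).
#' @export
generate_cohort <- function(spec,
                            hr_animal_sd = 12,
                            hr_period_sd = 4,
                            var_animal_sdlog = 0.10,
                            var_period_sdlog = 0.03,
                            rate_animal_sdlog = 0.30) {
  stopifnot(inherits(spec, "cohort_spec"))
  animals <- c(if (spec$n_control > 0) paste0("C", seq_len(spec$n_control)),
               if (spec$n_af > 0) paste0("A", seq_len(spec$n_af)))
  arms <- c(rep("control", spec$n_control), rep("af", spec$n_af))
  recs <- list()
  idx <- list()
  for (a in seq_along(animals)) {
    periods <- if (arms[a] == "control") spec$periods_control else spec$periods_af
    aseed <- derive_seed(spec$seed, a)
    draws <- with_seed(aseed, list(
      hr_off = stats::rnorm(1, 0, hr_animal_sd),
      var_mult = stats::rlnorm(1, 0, var_animal_sdlog),
      apb_mult = stats::rlnorm(1, 0, rate_animal_sdlog),
      af_mult = stats::rlnorm(1, 0, rate_animal_sdlog)))
    for (p in seq_along(periods)) {
      ps <- periods[[p]]
      pseed <- derive_seed(spec$seed, a, p)
      pdraw <- with_seed(derive_seed(pseed, 1), list(
        hr_noise = stats::rnorm(1, 0, hr_period_sd),
        var_noise = stats::rlnorm(1, 0, var_period_sdlog)))
      au <- ps$autonomic
      vm <- draws$var_mult * pdraw$var_noise
      au2 <- autonomic_params(
        mean_hr = max(150, au$mean_hr + draws$hr_off + pdraw$hr_noise),
        lf_mod_depth = min(0.45, au$lf_mod_depth * vm),
        hf_mod_depth = min(0.45, au$hf_mod_depth * vm),
        lf_freq = au$lf_freq, hf_freq = au$hf_freq,
        rr_jitter_cv = au$rr_jitter_cv * vm)
      ar <- ps$arrhythmia
      ar2 <- arrhythmia_params(
        apb_rate = ar$apb_rate * draws$apb_mult,
        apb_prematurity = ar$apb_prematurity,
        af_rate = ar$af_rate * draws$af_mult,
        af_duration_mean = ar$af_duration_mean,
        af_duration_sd = ar$af_duration_sd,
        af_rr_scale = ar$af_rr_scale, af_rr_cv = ar$af_rr_cv)
      rec <- simulate_recording(au2, ar2,
                                duration = ps$recording_duration,
                                represents_s = ps$represents_s,
                                seed = derive_seed(pseed, 2))
      rec$meta <- list(animal = animals[a], arm = arms[a], period = ps$label)
      nm <- paste0(animals[a], ".", ps$label)
      recs[[nm]] <- rec
      idx[[length(idx) + 1L]] <- data.frame(
        animal = animals[a], arm = arms[a], period = ps$label, name = nm,
        stringsAsFactors = FALSE)
    }
  }
  attr(recs, "index") <- do.call(rbind, idx)
  recs
}

#' Simulate one annotated recording
#'
#' Convenience wrapper: sinus beat train (IPFM), then AF episodes, then
#' APBs, as one seeded unit.
#'
#' @param autonomic An \code{\link{autonomic_params}}.
#' @param arrhythmia An \code{\link{arrhythmia_params}}.
#' @param duration Recording length, s.
#' @param represents_s Represented time, s.
#' @param seed Integer seed.
#' @return An \code{\link{annotated_recording}}.
#' @export
simulate_recording <- function(autonomic, arrhythmia = arrhythmia_params(),
                               duration = 3600, represents_s = duration,
                               seed = 1L) {
  bt <- generate_nn_times(autonomic, duration, seed = derive_seed(seed, 11))
  rec <- annotated_recording(bt, duration = duration,
                             represents_s = represents_s)
  rec <- inject_af_episodes(rec, arrhythmia, seed = derive_seed(seed, 12))
  rec <- inject_apbs(rec, arrhythmia, seed = derive_seed(seed, 13))
  rec
}

#' Simulate per-animal pacing-cycle induction outcomes
#'
#' Bernoulli outcome per stimulation cycle (probability
#' \code{protocol$per_cycle_induction_prob}), with lognormal induced-AF
#' durations for successful cycles; bookkeeping mirror of the daily
#' transesophageal burst-pacing sessions.
#'
#' @param protocol A \code{\link{stimulation_protocol}}.
#' @param n_animals Number of paced animals.
#' @param af_duration_mean,af_duration_sd Induced-episode duration moments, s.
#' @param seed Integer seed.
#' @return List of logical per-cycle outcome vectors (one per animal) with
#'   attribute \code{"durations"} (list of induced-AF durations).
#' @export
simulate_induction_outcomes <- function(protocol, n_animals,
                                        af_duration_mean = 123.2,
                                        af_duration_sd = 36.4,
                                        seed = 1L) {
  stopifnot(inherits(protocol, "stimulation_protocol"), n_animals >= 1)
  n_cycles <- protocol$cycles_per_day * protocol$n_days
  sdlog <- sqrt(log(1 + (af_duration_sd / af_duration_mean)^2))
  mulog <- log(af_duration_mean) - sdlog^2 / 2
  with_seed(seed, {
    out <- vector("list", n_animals)
    durs <- vector("list", n_animals)
    for (i in seq_len(n_animals)) {
      o <- stats::runif(n_cycles) < protocol$per_cycle_induction_prob
      out[[i]] <- o
      durs[[i]] <- stats::rlnorm(sum(o), mulog, sdlog)
    }
    attr(out, "durations") <- durs
    out
  })
}
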