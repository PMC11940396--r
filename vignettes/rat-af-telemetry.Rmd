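---
title: "Methods: simulating and analyzing AF burden in rat telemetry ECG"
author: "ratafib authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing AF burden in rat telemetry ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratafib)
```

This vignette documents the models, parameter choices and numerical
decisions behind `ratafib`. The package mirrors the analysis chain of a
long-term transesophageal atrial-pacing experiment in rats: continuous
telemetry ECG in four monitoring periods (before pacing, after pacing
weeks 1 and 2, and one week after the protocol), rule-based atrial
arrhythmia quantification, heart-rate-variability (HRV) analysis in
rat-specific bands, small-sample statistics, and housekeeping-normalized
gene expression.

## 1. The beat-train model

Sinus rhythm is generated by integral pulse frequency modulation (IPFM).
The instantaneous beat rate is

$$m(t) = \frac{\mathrm{HR}}{60}\left[1 + d_{LF}\sin(2\pi f_{LF}t+\varphi_1)
       + d_{HF}\sin(2\pi f_{HF}t+\varphi_2)\right],$$

and a beat fires whenever $\int_0^t m\,du$ crosses an integer. IPFM was
chosen because the study design constrains only the *location* of the
autonomic bands, not a generative model: IPFM gives directly controllable
LF/HF band power on the RR series while staying physiologically
interpretable (a modulated sinus-node firing rate). Multiplicative
lognormal white jitter (coefficient of variation `rr_jitter_cv`) models
beat-to-beat noise; the lognormal keeps RR positive at any CV and is
moment-matched so the jitter factor has mean 1 and CV exactly the
configured value.

Default autonomic parameters (units in parentheses):

| parameter | default | why |
|---|---|---|
| `mean_hr` (bpm) | 344.7 | reported pre-pacing mean 24-h heart rate of the paced arm |
| `lf_freq` (Hz) | 0.45 | centre of the rat LF band (0.3–0.6 Hz) |
| `hf_freq` (Hz) | 1.5 | inside the rat HF band (0.6–2.5 Hz), near respiratory rates |
| `lf_mod_depth` | 0.042 | see below |
| `hf_mod_depth` | 0.085 | see below |
| `rr_jitter_cv` | 0.10 | see below |

For a sinusoidal rate modulation of depth $d$ the RR series acquires a
component of standard deviation $\approx d\,\overline{RR}/\sqrt2$, and
white jitter of CV $c$ contributes $c\,\overline{RR}$, so the programmed
total SDNN is
$\overline{RR}\sqrt{d_{LF}^2/2 + d_{HF}^2/2 + c^2}$.
The defaults put SDNN at $\approx 21$ ms on a 174-ms mean RR — the
magnitude reported for this model before pacing — and the LF:HF variance
ratio at $\approx 0.25$, the reported sympathovagal balance. A
property-style test checks that the estimated SDNN recovers this
programmed value within 15 % across seeds.

**What the generator does not emulate.** Reported rat telemetry shows
SDNN ($\sim$21 ms) an order of magnitude above RMSSD ($\sim$4.5 ms),
which implies that most RR variance lives *below* the LF band
(very-low-frequency drift, thermoregulatory and activity rhythms). The
parameter set deliberately contains only LF and HF carriers plus white
jitter, so the simulated RMSSD and pNN5 run higher than the reported
values even when SDNN and LF/HF match. Passing tests therefore
demonstrate correct recovery of *programmed* variability structure, not
a claim that the simulator reproduces every time-domain feature of real
rat telemetry. The same applies to spectral units: band powers are
reported in absolute ms² from the periodogram; the reported LF and HF
table values (~2–9 "ms²") are not reproducible in absolute units from
the printed SDNN and were treated as qualitative targets (their ratio,
not their scale).

## 2. Arrhythmia injection

**APBs.** Counts are Poisson (`apb_rate`/hour of represented time). Each
APB advances an existing sinus beat to `apb_prematurity` (default 0.6)
times the preceding sinus RR and flags altered P morphology; the next
sinus beat keeps its original time (full, non-resetting compensatory
pause). This choice keeps all downstream sinus times fixed, so ground
truth stays trivially alignable with analysis output.

**AF episodes.** Onsets are Poisson (`af_rate`/24 h of represented
time); durations are lognormal, moment-matched to mean 123.2 s and SD
36.4 s — the reported induced-episode durations, used as the default for
spontaneous episodes too because no separate spontaneous-duration
statistics exist. Within an episode RR is `af_rr_scale` (default 0.7)
times the local sinus RR with lognormal CV `af_rr_cv` (default 0.15):
"rapid" and "irregular" made quantitative. Episodes shorter than three
beats are extended to three, matching the definitional minimum. The
*local sinus RR* used to scale episode rapidity is the median of the
last 11 sinus-bounded intervals before the onset — deliberately the
same reference window the classifier uses (Section 4), so that the
programmed rapidity ratio survives analysis; an earlier draft that used
a different window produced borderline rapidity ratios whenever 10 %
RR jitter made two 11-sample medians disagree.

**Desk-scale time compression.** A recording can *represent* more time
than it spans (default periods: 3600 s standing for 24 h) so that tests
and examples run at desk scale. Rates keep their natural per-hour /
per-24 h units against the represented time; injected episode durations
are compressed by `duration/represents_s` so the *fraction* of recording
time spent in AF matches the represented day (leaving durations
uncompressed would let a day's worth of 2-min episodes swallow a quarter
of a 1-h recording and distort mean heart rate); `burden_24h()` converts
counts and episode durations back to the per-24 h scale. With
`represents_s = duration` (no compression) nothing is rescaled.

## 3. Waveform rendering and beat detection

Rendering places Gaussian-lobe P/QRS/T templates at each beat time
(R 1.0 mV with narrow Q/S lobes, P 0.10 mV ending ~25 ms before R, short
T merged close to the QRS as in rat ECG). AF beats omit the P template;
APBs carry an inverted ectopic P — the classic morphology of a low-atrial
ectopic focus — which gives the P-assessment a clean "present but
non-sinus" signal. Sampling below 500 Hz is rejected (a rat QRS spans
~15 ms).

Detection is a Pan–Tompkins-style chain (band-pass 10–80 Hz via a
2nd-order Butterworth run through `signal::filtfilt`, derivative,
squaring, 20-ms moving-window integration, adaptive two-level threshold
with running signal/noise peak estimates, 60-ms refractory), with the
final R time refined to the extremum of the band-passed trace. Rodent
telemetry detectors are typically lab-written and undocumented, so this
detector is config-exposed and validated only against synthetic ground
truth (exact detection on clean traces; sensitivity and PPV ≥ 0.99 at
20 dB SNR in the test suite).

P-wave assessment learns a sinus P template from regular-RR beats and
computes the maximum normalized cross-correlation of each pre-QRS window
with it over ±10 ms lags. Two practical details matter at rat rates:
the search window is truncated to start no earlier than 60 ms after the
*preceding* R peak, otherwise the previous beat's T wave leaks into the
window during rapid AF and masquerades as a P wave; and presence
requires both |correlation| ≥ 0.5 and a matched-filter amplitude at
least half the template's, so noise-only windows do not correlate their
way into P calls. Morphology match additionally requires *signed*
correlation ≥ 0.8; an inverted ectopic P is thus "present, mismatched".
Windows too short to judge (very premature beats) are flagged
indeterminate rather than guessed.

## 4. Rhythm classification

Candidate AF runs are maximal runs of absent-P beats. A run is AF iff it
has ≥ 3 beats (definitional, not tunable below 3), median within-run RR
< 0.75 × the local sinus median RR, and within-run RR CV > 0.08. The
local sinus median is a sliding window of the last 11 intervals bounded
by sinus beats, falling back to a global median when unavailable (an
all-arrhythmic recording warns and uses the global RR median). Absent-P
runs that fail the AF criteria are labeled APB beat-by-beat, so every
arrhythmic beat stays accounted for; isolated premature beats
(< 0.85 × local sinus RR) with mismatched P morphology are APBs;
physiologically impossible RR (< 40 ms) flags an artifact. One
detection-robustness rule: a *single* present-P beat flanked by absent-P
beats on both sides is treated as a spurious P call and bridged into the
run — without it, a ~1 % P false-positive rate inside AF fragments long
episodes into overlapping pieces. In RR-native mode (exact flags) the
rule never fires on generator output, because injected episodes are
always separated by more than one sinus beat.

Episode segmentation follows the study convention: an episode runs from
its first arrhythmic beat to the first subsequent sinus beat (recording
end if none). `burden_24h()` pools the whole recording and rescales to
24 h — the study reports "over 24 h intervals" without stating the
aggregation, and pooling-then-scaling is the variance-minimizing choice
for a stationary rate. Inducibility is bookkeeping over the pacing
schedule (15 daily cycles × 10 days by default): per-animal percentage
of cycles followed by AF, and the cohort share of animals with any
induced episode, reported to one decimal.

## 5. HRV

Non-normal intervals are excluded before any HRV computation: an
interval inherits the worst label of its two bounding beats, and one
neighbouring interval on each side (`exclusion_margin = 1`) is dropped
with it. Original timestamps are retained — no gap splicing — because
the spectral estimator works on the native uneven time base.

Time domain: SDNN (SD with $n-1$ denominator), RMSSD, and pNN5 with a
*strict* > 5 ms comparison, following the wording "differed by > 5 ms";
a 5.000-ms difference does not count. Metrics that cannot be computed
(fewer than 2–3 intervals) are NA-flagged, never zero-filled.

Frequency domain: a Lomb–Scargle periodogram evaluated on the standard
grid (spacing 1/span up to the pseudo-Nyquist frequency, half the mean
beat rate), normalized so that the PSD integrates to the series variance
— verified by a Parseval-style test (within 2 % on an evenly sampled
series). Lomb–Scargle on the native time base was preferred over
interpolation + FFT to avoid resampling bias at rat beat rates, where
the HF band (up to 2.5 Hz) sits close to half the beat rate (~2.8 Hz);
the interpolation + FFT path ships behind
`hrv_config(spectral_method = "interp_fft")` for comparison. Band powers
are integrated over LF 0.3–0.6 Hz and HF 0.6–2.5 Hz; LF/HF is NA when
HF is zero.

Epoching: the study does not state its HRV window, so the package uses
5-min epochs aggregated by per-metric medians (robust to a single
disturbed epoch), with an epoch valid only if it retains ≥ 80 % of the
expected NN count. These are package choices, configurable in
`hrv_config()`.

## 6. Statistics and expression

The normality gate is Shapiro–Wilk at α = 0.05 per sample (the study
names no specific test); any non-normal, degenerate or tiny sample
routes to the nonparametric branch. Between groups: Welch t (via
`t.test`) or an exact Mann–Whitney U. The exact U enumerates all
$\binom{n_x+n_y}{n_x}$ assignments of the pooled *mid-ranks* — exact
with ties, feasible and instant at the study's 5 + 7 — and doubles the
smaller tail (capped at 1); beyond 14 observations it switches to the
tie-corrected normal approximation. Within groups: one-way
repeated-measures ANOVA (`aov` with an error stratum per subject;
degenerate zero-error cases resolved explicitly) or Friedman
(`friedman.test`, tie-corrected), gated the same way. Two-sided p values
throughout and no multiple-testing correction, matching the study's
reporting; sphericity corrections are deliberately omitted because only
omnibus p values are mirrored.

Expression: normalized value = raw gene level / same-animal GAPDH
(linear ratio — the reported table values near 1 are consistent with
ratio units); a `2^-ΔCt`-style path is available via `method = "ddct"`.
Animals without positive GAPDH are excluded with a warning. Group
summaries are mean ± SEM ($n-1$ SD), compared per gene by Welch t. The
simulator draws per-animal ratios from Gaussian distributions whose
means/SEMs default to the reported four-gene panel (Hcn1, Hcn2, Hcn4,
Pitx2).

## 7. Cohort defaults and the programmed trends

`default_period_specs()` encodes the study's between-period structure:
AF-arm mean heart rate declining 344.7 → 330.6 → 320.4 → 318.0 bpm and
overall RR variability rising in proportion to the reported SDNN
trajectory (20.69 → 26.07 ms, applied as a common scale on both
modulation depths and jitter); APB rate rising (0.5 → 4 /h); AF absent
before pacing and rising 3 → 8 episodes/24 h afterwards. The control arm
is flat at 320 bpm with zero AF. Per-animal physiology is drawn once per
animal — heart-rate offset (SD 12 bpm, consistent with the reported
between-animal SEMs), lognormal variability and arrhythmia-rate
multipliers — and reused across periods, so between-period contrasts
behave like genuine repeated measures; small per-period noise (4 bpm,
3 % variability) sets the within-subject error. The exact APB/AF rate
trajectories are package choices: the study reports these trends only
graphically, without numeric per-period rates.

Test problem sizes are deliberately desk-scale: 1-h compressed
recordings, 5 + 7 animals, 20-seed power checks, and 2000-replicate null
calibrations of the within-group tests at the study's n = 7, k = 4.

## 8. Known limitations

* The ECG model is morphological, not electrophysiological: no pacing
  artifacts, no ventricular arrhythmias, no atrial flutter vs AF
  distinction, no T-wave analysis.
* The simulator has no VLF/circadian component (Section 1), so absolute
  RMSSD/pNN5 levels do not match real rat telemetry.
* P-wave assessment assumes the rendered template family; on real data
  the thresholds (presence 0.5, morphology 0.8) would need re-tuning.
  P-wave absence is often confirmed visually in telemetry studies; the
  template-correlation operationalization is this package's.
* Repeated-measures inference is omnibus-only; no post-hoc pairwise
  comparisons or sphericity corrections.
* Induced-vs-spontaneous AF is distinguished by schedule bookkeeping
  (stimulation windows), not by morphology.
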