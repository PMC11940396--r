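# Shared helpers for building small in-code fixtures.

# metronomic sinus recording: constant RR, no modulation
metronome_recording <- function(mean_hr = 300, duration = 600, seed = 1,
                                represents_s = duration) {
  annotated_recording(
    generate_nn_times(autonomic_params(mean_hr, 0, 0, rr_jitter_cv = 0),
                      duration, seed),
    duration = duration, represents_s = represents_s)
}

# physiologic sinus recording with default autonomic modulation
sinus_recording <- function(duration = 600, seed = 1,
                            represents_s = duration, ...) {
  annotated_recording(
    generate_nn_times(autonomic_params(...), duration, seed),
    duration = duration, represents_s = represents_s)
}

# match detected af episodes against ground truth by onset time;
# tol_s ~ one beat at rat rates
episode_scores <- function(got, truth, tol_s = 0.25) {
  gs <- got$start_s[got$type == "af"]
  ts <- truth$start_s[truth$type == "af"]
  if (!length(ts)) return(c(recall = NA_real_, precision = NA_real_))
  m <- outer(gs, ts, function(a, b) abs(a - b) < tol_s)
  c(recall = sum(apply(m, 2, any)) / length(ts),
    precision = if (length(gs)) sum(apply(m, 1, any)) / length(gs)
                else NA_real_)
}

# classify + segment a recording from its own annotations (rr-native path)
classify_recording <- function(rec, cfg = classifier_config()) {
  rr <- diff(rec$beat_times) * 1000
  labels <- classify_beats(rr, rec$p_present, rec$p_morph_match, cfg)
  list(labels = labels,
       episodes = segment_episodes(labels, rec$beat_times))
}
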