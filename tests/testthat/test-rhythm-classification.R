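# Build aligned (rr, p_present, p_morph) vectors for rule tests:
# a sinus backbone at 200 ms with an inserted absent-P run of given RRs.
rule_fixture <- function(run_rr, n_sinus_before = 20, n_sinus_after = 20,
                         sinus_rr = 200) {
  rr <- c(rep(sinus_rr, n_sinus_before), run_rr, rep(sinus_rr, n_sinus_after))
  n <- length(rr) + 1
  pp <- rep(TRUE, n)
  run_beats <- (n_sinus_before + 2):(n_sinus_before + 1 + length(run_rr))
  pp[run_beats] <- FALSE
  list(rr = rr, p_present = pp, p_morph = pp, run_beats = run_beats)
}

test_that("the AF rule needs >= 3 absent-P beats, rapid and irregular RR", {
  # 5-beat absent-P run at ~130 ms inside 200 ms sinus, CV ~ 0.1 -> af
  fx <- rule_fixture(c(105, 145, 115, 135, 125))
  lab <- classify_beats(fx$rr, fx$p_present, fx$p_morph)
  expect_true(all(lab[fx$run_beats] == "af"))
  expect_true(all(lab[-fx$run_beats] == "sinus"))
  # 2-beat absent-P run fails "at least three" -> apb
  fx2 <- rule_fixture(c(120))
  lab2 <- classify_beats(fx2$rr, fx2$p_present, fx2$p_morph)
  expect_true(all(lab2[fx2$run_beats] == "apb"))
  expect_false(any(lab2 == "af"))
  # rapid but regular run (CV < 0.08) is not AF
  fx3 <- rule_fixture(rep(120, 5))
  lab3 <- classify_beats(fx3$rr, fx3$p_present, fx3$p_morph)
  expect_false(any(lab3 == "af"))
  # slow absent-P run is not AF
  fx4 <- rule_fixture(c(185, 210, 190, 205))
  lab4 <- classify_beats(fx4$rr, fx4$p_present, fx4$p_morph)
  expect_false(any(lab4 == "af"))
})

test_that("an isolated premature beat with mismatched P is an APB", {
  rr <- rep(200, 40)
  rr[20] <- 140  # 0.7 x sinus RR
  n <- length(rr) + 1
  pp <- rep(TRUE, n); pm <- rep(TRUE, n)
  pm[21] <- FALSE  # beat ending the short interval
  lab <- classify_beats(rr, pp, pm)
  expect_identical(lab[21], "apb")
  expect_identical(sum(lab == "apb"), 1L)
  # same prematurity with matching morphology stays sinus
  lab2 <- classify_beats(rr, pp, rep(TRUE, n))
  expect_false(any(lab2 == "apb"))
})

test_that("an all-absent-P recording falls back to the global median", {
  rr <- rep(c(100, 120, 95, 130), 10)
  n <- length(rr) + 1
  expect_warning(lab <- classify_beats(rr, rep(FALSE, n), rep(FALSE, n)),
                 "median")
  expect_true(all(lab %in% c("af", "apb")))
})

test_that("episode boundaries follow the first-subsequent-sinus rule", {
  # af beats at 10.0..12.5 s, next sinus at 12.7 -> duration 2.7 s
  times <- c(9.6, 9.8, 10.0, 10.6, 11.2, 11.9, 12.5, 12.7, 12.9)
  labels <- c("sinus", "sinus", rep("af", 5), "sinus", "sinus")
  eps <- segment_episodes(labels, times)
  expect_identical(nrow(eps), 1L)
  expect_equal(eps$start_s, 10.0)
  expect_equal(eps$end_s, 12.7)
  expect_equal(eps$duration_s, 2.7)
  expect_identical(eps$n_beats, 5L)
  # no arrhythmic labels -> empty
  expect_identical(nrow(segment_episodes(rep("sinus", 5), 1:5)), 0L)
  # af run at the recording end closes at the last beat
  eps2 <- segment_episodes(c("sinus", rep("af", 4)), c(1, 2, 2.1, 2.2, 2.3))
  expect_equal(eps2$end_s, 2.3)
})

test_that("episodes are recovered exactly on clean synthetic recordings", {
  for (s in 1:5) {
    rec <- simulate_recording(
      autonomic_params(),
      arrhythmia_params(apb_rate = 4, af_rate = 6 * 24, af_duration_mean = 30,
                        af_duration_sd = 10),
      duration = 3600, seed = s)
    out <- classify_recording(rec)
    sc <- episode_scores(out$episodes, rec$true_episodes)
    expect_equal(unname(sc["recall"]), 1)
    expect_equal(unname(sc["precision"]), 1)
    # boundaries within one beat of ground truth
    got <- out$episodes[out$episodes$type == "af", ]
    truth <- rec$true_episodes[rec$true_episodes$type == "af", ]
    for (k in seq_len(nrow(truth))) {
      j <- which.min(abs(got$start_s - truth$start_s[k]))
      expect_lt(abs(got$start_s[j] - truth$start_s[k]), 0.25)
      expect_lt(abs(got$end_s[j] - truth$end_s[k]), 0.25)
    }
    # hard invariants: no af episode under 3 beats; ordered, non-overlapping
    af <- out$episodes[out$episodes$type == "af", ]
    expect_true(all(af$n_beats >= 3))
    if (nrow(af) > 1)
      expect_true(all(af$start_s[-1] >= af$end_s[-nrow(af)]))
  }
})

test_that("burden normalizes to 24 h and flags AF presence", {
  # 12 af episodes across a 72 h recording -> 4 episodes / 24 h
  times <- seq(0, 72 * 3600, by = 0.2)
  labels <- rep("sinus", length(times))
  eps <- data.frame(start_s = seq(1000, 12000, by = 1000),
                    end_s = seq(1000, 12000, by = 1000) + 60,
                    type = "af", n_beats = 300)
  eps$duration_s <- eps$end_s - eps$start_s
  b <- burden_24h(eps, labels, times, duration = 72 * 3600)
  expect_equal(b$af_episodes_per_24h, 4.0)
  expect_true(b$af_present)
  # constant 200 ms RR -> 300 bpm
  b2 <- burden_24h(empty_ep <- segment_episodes(rep("sinus", 5), (0:4) * 0.2),
                   rep("sinus", 5), (0:4) * 0.2, duration = 0.8)
  expect_equal(b2$mean_hr_24h, 300)
  expect_false(b2$af_present)
  expect_identical(b2$apbs_per_24h, 0)
  expect_error(burden_24h(empty_ep, "sinus", 0, duration = 0), "duration")
  # invariance under uniform time compression when the recording declares
  # the represented time: per-24h counts and episode durations unchanged
  b3 <- burden_24h(within(eps, {start_s <- start_s / 2; end_s <- end_s / 2
                                duration_s <- duration_s / 2}),
                   labels, times / 2, duration = 36 * 3600,
                   represents = 72 * 3600)
  expect_equal(b3$af_episodes_per_24h, b$af_episodes_per_24h)
  expect_equal(b3$mean_af_duration, b$mean_af_duration)
})

test_that("inducibility reproduces the six-of-seven worked example", {
  out <- inducibility(c(rep(list(c(TRUE, FALSE, FALSE)), 6),
                        list(rep(FALSE, 3))))
  expect_identical(out$pct_animals_inducible, 85.7)
  expect_identical(out$per_animal$animal_inducible,
                   c(rep(TRUE, 6), FALSE))
  # 0 of 15 and 15 of 15 cycles
  expect_identical(inducibility(list(rep(FALSE, 15)))$per_animal$cycle_inducibility_pct, 0)
  expect_identical(inducibility(list(rep(TRUE, 15)))$per_animal$cycle_inducibility_pct, 100)
  expect_error(inducibility(list()), "empty")
})

test_that("simulated induction outcomes match the protocol bookkeeping", {
  proto <- stimulation_protocol()
  out <- simulate_induction_outcomes(proto, 7, seed = 2)
  expect_length(out, 7)
  expect_true(all(lengths(out) == proto$cycles_per_day * proto$n_days))
  ind <- inducibility(out)
  expect_true(ind$cycle_inducibility_mean > 20 &&
                ind$cycle_inducibility_mean < 70)
  expect_identical(length(attr(out, "durations")), 7L)
})
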