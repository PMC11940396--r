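test_that("exclusion drops intervals touching non-sinus beats plus margin", {
  rr <- data.frame(time_s = (0:19) * 0.2, rr_ms = rep(200, 20))
  labels <- rep("sinus", 21)
  expect_identical(exclude_non_normal(rr, labels), rr)
  # one apb at beat k = 10 contaminates intervals 9 and 10 (0-based k-1, k);
  # the default margin of 1 extends the cut to intervals 8..11
  labels[10] <- "apb"
  nn <- exclude_non_normal(rr, labels)
  dropped <- setdiff(seq_len(20), as.integer(rownames(nn)))
  expect_identical(dropped, 8:11)
})

test_that("post-exclusion SDNN matches the uncontaminated twin series", {
  rec <- sinus_recording(duration = 600, seed = 9)
  twin <- inject_apbs(rec, arrhythmia_params(apb_rate = 5 * 30), seed = 2)
  expect_gt(sum(twin$beat_labels == "apb"), 10)  # ~5% contamination
  sd_clean <- time_domain(rr_series(rec$beat_times)$rr_ms)$sdnn
  nn <- exclude_non_normal(rr_series(twin$beat_times), twin$beat_labels)
  sd_ex <- time_domain(nn$rr_ms)$sdnn
  expect_lt(abs(sd_ex - sd_clean) / sd_clean, 0.05)
})

test_that("time-domain metrics match direct formulas", {
  td0 <- time_domain(rep(180, 50))
  expect_equal(c(td0$sdnn, td0$rmssd, td0$pnn), c(0, 0, 0))
  # alternating 160/170: every |delta| = 10 > 5
  td1 <- time_domain(rep(c(160, 170), 25))
  expect_equal(td1$rmssd, 10)
  expect_equal(td1$pnn, 100)
  # random series vs independent second-path formulas
  set.seed(4)
  x <- rnorm(500, 180, 8)
  td <- time_domain(x)
  d <- x[-1] - x[-length(x)]
  expect_equal(td$sdnn, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-9)
  expect_equal(td$rmssd, sqrt(sum(d^2) / length(d)), tolerance = 1e-9)
  expect_equal(td$pnn, 100 * sum(abs(d) > 5) / length(d), tolerance = 1e-9)
  # strict inequality at exactly 5 ms
  expect_equal(time_domain(cumsum(c(160, rep(c(5, -5), 10))))$pnn, 0)
  # insufficient data is flagged, not zero-filled
  expect_true(is.na(time_domain(c(180))$sdnn))
  expect_true(is.na(time_domain(c(180, 190))$rmssd))
})

test_that("band powers land in the programmed bands", {
  # pure 1.5 Hz HF modulation
  t <- generate_nn_times(autonomic_params(330, 0, 0.1, hf_freq = 1.5,
                                          rr_jitter_cv = 0), 300, 3)
  rr <- rr_series(t)
  fd <- frequency_domain(rr$rr_ms, rr$time_s)
  expect_gte(fd$hf / (fd$lf + fd$hf), 0.9)
  # pure 0.45 Hz LF modulation
  t2 <- generate_nn_times(autonomic_params(330, 0.1, 0, lf_freq = 0.45,
                                           rr_jitter_cv = 0), 300, 3)
  rr2 <- rr_series(t2)
  fd2 <- frequency_domain(rr2$rr_ms, rr2$time_s)
  expect_gte(fd2$lf / fd2$hf, 5)
  # constant NN: numerical floor
  fdc <- frequency_domain(rep(180, 200), (1:200) * 0.18)
  expect_lte(fdc$lf, 1e-6)
  expect_lte(fdc$hf, 1e-6)
  expect_true(is.na(fdc$lf_hf))
  expect_error(frequency_domain(rep(180, 50), (1:50) * 0.18), "64")
  expect_error(frequency_domain(rep(180, 100), (1:100) * 0.1), "30 s")
})

test_that("spectral estimate preserves variance (Parseval) within 2%", {
  set.seed(1)
  x <- 180 + 5 * sin(2 * pi * 1.2 * (1:512) * 0.18) + rnorm(512, 0, 3)
  tt <- (1:512) * 0.18
  fd <- frequency_domain(x, tt)
  expect_lt(abs(fd$total_power - stats::var(x)) / stats::var(x), 0.02)
  # and the interpolation+FFT path agrees on band placement
  fd2 <- frequency_domain(x, tt, hrv_config(spectral_method = "interp_fft"))
  expect_gt(fd2$hf / (fd2$lf + fd2$hf), 0.8)
})

test_that("estimated HF power is monotone in programmed HF depth", {
  hf <- vapply(c(0.03, 0.06, 0.09, 0.12), function(d) {
    t <- generate_nn_times(autonomic_params(330, 0, d, rr_jitter_cv = 0.02),
                           300, 17)
    rr <- rr_series(t)
    frequency_domain(rr$rr_ms, rr$time_s)$hf
  }, numeric(1))
  expect_true(all(diff(hf) > 0))
})

test_that("programmed SDNN is recovered within 15% across seeds", {
  # defaults programme a total RR CV of sqrt(lf^2/2 + hf^2/2 + jitter^2)
  p <- autonomic_params()
  cv <- sqrt(p$lf_mod_depth^2 / 2 + p$hf_mod_depth^2 / 2 + p$rr_jitter_cv^2)
  programmed <- cv * 60000 / p$mean_hr
  est <- vapply(1:20, function(s) {
    t <- generate_nn_times(p, 300, s)
    time_domain(rr_series(t)$rr_ms)$sdnn
  }, numeric(1))
  expect_lt(abs(mean(est) - programmed) / programmed, 0.15)
})

test_that("epoch aggregation uses medians and flags rejected epochs", {
  rr <- data.frame(time_s = seq(0, 1499.8, by = 0.2),
                   rr_ms = rep(200, 7500))
  rr$rr_ms <- rr$rr_ms + rep(c(-2, 2), length.out = 7500)
  agg <- aggregate_recording(rr, hrv_config(epoch_length = 300), freq = FALSE)
  expect_identical(agg$n_epochs, 5L)
  expect_identical(agg$n_valid, 5L)
  # identical epochs: aggregate equals the epoch value
  expect_equal(agg$sdnn, agg$epochs$sdnn[1])
  # one outlier epoch among identical ones leaves the median unchanged
  rr2 <- rr
  rr2$rr_ms[rr2$time_s >= 1200] <- rr2$rr_ms[rr2$time_s >= 1200] * 3
  agg2 <- aggregate_recording(rr2, hrv_config(epoch_length = 300),
                              freq = FALSE)
  expect_equal(agg2$sdnn, agg$sdnn)
  # an epoch with too few intervals is rejected
  rr3 <- rr[rr$time_s < 350 & !(rr$time_s > 310 & rr$time_s < 590), ]
  agg3 <- aggregate_recording(rr3, hrv_config(epoch_length = 300),
                              freq = FALSE)
  expect_gte(agg3$n_rejected, 1L)
  # empty input: undefined-flagged
  agg4 <- aggregate_recording(rr[0, ], freq = FALSE)
  expect_true(is.na(agg4$sdnn))
})

test_that("HRV metrics are invariant under time translation", {
  t <- generate_nn_times(autonomic_params(), 300, 5)
  rr <- rr_series(t)
  rr_shift <- rr; rr_shift$time_s <- rr_shift$time_s + 1000
  td <- time_domain(rr$rr_ms); td2 <- time_domain(rr_shift$rr_ms)
  expect_equal(td$sdnn, td2$sdnn)
  fd <- frequency_domain(rr$rr_ms, rr$time_s)
  fd2 <- frequency_domain(rr_shift$rr_ms, rr_shift$time_s)
  expect_equal(fd$lf, fd2$lf, tolerance = 1e-6)
  expect_equal(fd$hf, fd2$hf, tolerance = 1e-6)
})
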