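test_that("band-pass rejects DC, passes mid-band, and guards Nyquist", {
  fs <- 2000
  dc <- emg_trace(rep(1, 8000), fs = fs)
  out <- emg_bandpass(dc)
  expect_lt(max(abs(out$samples[3000:5000])), 1e-6)

  t <- seq_len(4000) / fs
  s100 <- emg_trace(sin(2 * pi * 100 * t), fs = fs)
  y <- emg_bandpass(s100)$samples[500:3500]
  rms_in <- sqrt(mean(sin(2 * pi * 100 * t[500:3500])^2))
  expect_lt(abs(sqrt(mean(y^2)) / rms_in - 1), 0.05)

  expect_error(emg_bandpass(s100, hi = 1200),
               class = "stopcancel_invalid_parameter")
})

test_that("envelope is the rectified low-passed profile", {
  fs <- 2000
  z <- emg_envelope(emg_trace(rep(0, 2000), fs = fs))
  expect_equal(z$samples, rep(0, 2000))

  cst <- emg_envelope(emg_trace(rep(0.7, 4000), fs = fs))
  expect_lt(max(abs(cst$samples[1000:3000] - 0.7)), 0.7 * 0.01)

  t <- seq_len(8000) / fs
  A <- 2
  env <- emg_envelope(emg_trace(A * sin(2 * pi * 150 * t), fs = fs))
  expect_lt(abs(mean(env$samples[2000:6000]) - 2 * A / pi), 0.05 * 2 * A / pi)
  expect_true(all(env$samples >= 0))
})

test_that("burst detection thresholds, merges close bursts, and reports peaks", {
  # flat noise-free trace: no bursts
  flat <- emg_trace(rep(0.02, 2000), fs = 2000, t0_s = -0.1)
  expect_equal(nrow(detect_bursts(flat)), 0)

  # two bursts separated by a 10 ms sub-threshold gap merge into one
  tr <- rect_envelope(bumps = list(
    list(from_ms = 100, to_ms = 150, amp = 1),
    list(from_ms = 160, to_ms = 210, amp = 1)))
  b <- detect_bursts(tr)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$onset_ms - 100), 1)
  expect_gt(b$offset_ms, 209)

  # a 30 ms gap stays two bursts
  tr2 <- rect_envelope(bumps = list(
    list(from_ms = 100, to_ms = 150, amp = 1),
    list(from_ms = 180, to_ms = 230, amp = 1)))
  expect_equal(nrow(detect_bursts(tr2)), 2)

  # bursts are disjoint with gaps >= merge window after merging
  b2 <- detect_bursts(tr2)
  expect_true(all(diff(c(rbind(b2$onset_ms, b2$offset_ms))) >= 0))
  expect_true(b2$onset_ms[2] - b2$offset_ms[1] >= 20)

  # too-short trial
  expect_error(detect_bursts(emg_trace(rep(0, 50), fs = 2000)),
               class = "stopcancel_processing_error")
})

test_that("burst detection matches the brute-force per-sample oracle exactly", {
  set.seed(42)
  fs <- 2000
  for (i in 1:500) {
    n <- sample(400:2000, 1)
    base <- abs(rnorm(n, 0, 0.02))
    n_b <- sample(0:3, 1)
    for (k in seq_len(n_b)) {
      at <- sample(seq_len(n - 80), 1)
      len <- sample(20:80, 1)
      base[at:(at + len - 1)] <- base[at:(at + len - 1)] + runif(1, 0.2, 1)
    }
    env <- pmax(base, 0)
    got <- detect_bursts(emg_trace(env, fs = fs, t0_s = -0.05))
    want <- brute_force_bursts(env, fs = fs, t0_s = -0.05)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$offset_ms, want$offset_ms)
      expect_equal(got$peak_ms, want$peak_ms)
      expect_equal(got$peak_amp, want$peak_amp)
    }
  }
})

test_that("generator bursts are detected with envelope-limited timing accuracy", {
  # The 10 Hz envelope smoothing spreads burst edges over tens of ms, so
  # threshold-crossing onsets carry a systematic lag of that order; peak
  # times, which drive Cancel Time, are recovered essentially unbiased.
  p <- test_params()
  sim <- simulate_session(p, generate_session("CRT", seed = 51, n_trials = 60,
                                              n_practice = 0),
                          seed = 52, emg = TRUE)
  proc <- emg_process_session(sim)
  err_on <- proc$trials$emg_onset_ms - sim$truth$true_onset_ms
  err_pk <- proc$trials$emg_peak_ms - sim$truth$true_peak_ms
  err_on <- err_on[is.finite(err_on)]; err_pk <- err_pk[is.finite(err_pk)]
  expect_gt(length(err_on), 40)
  expect_lt(abs(mean(err_pk)), 5)          # peak timing: unbiased
  expect_lt(abs(mean(err_on)), 35)         # onset: smoothing-limited lag
  expect_lt(sd(err_on), 15)
})

test_that("the response-generating burst is the last causally-linked burst", {
  bursts <- tibble::tibble(onset_ms = 250, offset_ms = 380, peak_ms = 300,
                           peak_amp = 1)
  expect_equal(select_rt_burst(bursts, press_ms = 400)$onset_ms, 250)

  late <- tibble::tibble(onset_ms = 370, offset_ms = 420, peak_ms = 390,
                         peak_amp = 1)
  expect_null(select_rt_burst(late, press_ms = 400))  # only 30 ms lead

  two <- tibble::tibble(onset_ms = c(200, 300), offset_ms = c(260, 360),
                        peak_ms = c(230, 330), peak_amp = c(1, 0.9))
  expect_equal(select_rt_burst(two, press_ms = 400)$onset_ms, 300)

  # exactly 50 ms before the press still qualifies ("at least 50 ms")
  edge <- tibble::tibble(onset_ms = 350, offset_ms = 420, peak_ms = 380,
                         peak_amp = 1)
  expect_equal(select_rt_burst(edge, press_ms = 400)$onset_ms, 350)
})

test_that("prEMG classification applies all three criteria", {
  b <- tibble::tibble(onset_ms = 150, offset_ms = 320, peak_ms = 280,
                      peak_amp = 0.5)
  # a press means a failed stop, never prEMG
  expect_null(detect_premg(b, ssd_ms = 200, press_occurred = TRUE,
                           ref_peak = 1))
  # peak before the stop signal: inhibition was not stop-triggered
  early <- tibble::tibble(onset_ms = 100, offset_ms = 220, peak_ms = 180,
                          peak_amp = 0.5)
  expect_null(detect_premg(early, ssd_ms = 200, press_occurred = FALSE,
                           ref_peak = 1))
  # amplitude below 10% of the CRT reference
  weak <- tibble::tibble(onset_ms = 150, offset_ms = 320, peak_ms = 280,
                         peak_amp = 0.05)
  expect_null(detect_premg(weak, ssd_ms = 200, press_occurred = FALSE,
                           ref_peak = 1))
  # all three pass
  ev <- detect_premg(b, ssd_ms = 200, press_occurred = FALSE, ref_peak = 1)
  expect_equal(ev$cancel_time_ms, 80)
  expect_equal(ev$peak_amp_norm, 0.5)
  expect_error(detect_premg(b, 200, FALSE, ref_peak = 0),
               class = "stopcancel_invalid_reference")
})

test_that("Cancel Time is peak minus SSD and must be positive", {
  expect_equal(cancel_time(tibble::tibble(peak_ms = 350), 200), 150)
  expect_error(cancel_time(tibble::tibble(peak_ms = 199), 200),
               class = "stopcancel_contract_violation")
})

test_that("normalisation scales to the mean CRT reference peak", {
  peaks <- c(0.8, 1.0, 1.2)
  envs <- list(emg_trace(c(0, 0.8, 0)), emg_trace(c(0, 1.0, 0)),
               emg_trace(c(0, 1.2, 0)))
  nm <- normalise_profiles(envs, peaks)
  norm_peaks <- vapply(nm$envelopes, function(e) max(e$samples), numeric(1))
  expect_equal(mean(norm_peaks), 1, tolerance = 1e-12)

  z <- normalise_profiles(list(emg_trace(rep(0, 10))), peaks)
  expect_equal(z$envelopes[[1]]$samples, rep(0, 10))

  nm2 <- normalise_profiles(lapply(envs, function(e) {
    e$samples <- 2 * e$samples; e
  }), 2 * peaks)
  expect_equal(lapply(nm2$envelopes, `[[`, "samples"),
               lapply(nm$envelopes, `[[`, "samples"))

  expect_error(normalise_profiles(envs, numeric(0)),
               class = "stopcancel_processing_error")
})

test_that("mean profiles align, average and carry a pointwise CI", {
  fs <- 2000
  mk <- function(shift_ms) {
    x <- rep(0, 1000)
    t_ms <- (seq_len(1000) - 1) / fs * 1000
    x[t_ms >= 100 + shift_ms & t_ms <= 200 + shift_ms] <- 1
    emg_trace(x, fs = fs, t0_s = 0)
  }
  # identical trials: zero-width CI
  mp <- mean_profile(list(mk(0), mk(0)), align_ms = c(0, 0))
  expect_equal(mp$ci_hi - mp$ci_lo, rep(0, nrow(mp)))

  # two rectangles offset by 50 ms: mean is their pointwise average
  mp2 <- mean_profile(list(mk(0), mk(50)), align_ms = c(0, 0))
  t_in_both <- mp2$time_ms >= 150 & mp2$time_ms <= 200
  t_in_one <- (mp2$time_ms >= 100 & mp2$time_ms < 150) |
    (mp2$time_ms > 200 & mp2$time_ms <= 250)
  expect_true(all(abs(mp2$mean[t_in_both] - 1) < 1e-9))
  expect_true(all(abs(mp2$mean[t_in_one] - 0.5) < 1e-9))

  # peak alignment puts every peak at t = 0
  tri <- function(center_ms) {
    t_ms <- (seq_len(1000) - 1) / fs * 1000
    emg_trace(pmax(0, 1 - abs(t_ms - center_ms) / 50), fs = fs)
  }
  trials <- list(tri(150), tri(300))
  peaks <- vapply(trials, function(e) {
    t_ms <- (seq_along(e$samples) - 1) / fs * 1000
    t_ms[which.max(e$samples)]
  }, numeric(1))
  mp3 <- mean_profile(trials, align_ms = peaks, align = "PEAK")
  expect_lt(abs(mp3$time_ms[which.max(mp3$mean)]), 1000 / fs)

  expect_error(mean_profile(list(mk(0)), 0),
               class = "stopcancel_processing_error")
})

test_that("prEMG proportion is invariant to uniform amplitude rescaling", {
  p <- race_params()
  sim <- simulate_stop_trials(p, n_per_cell = 40, seed = 61, emg = TRUE)
  crt <- simulate_session(p, generate_session("CRT", seed = 62,
                                              n_trials = 24, n_practice = 0),
                          seed = 63, emg = TRUE)
  scale_all <- function(s, f) {
    s$traces <- lapply(s$traces, function(m) m * f)
    s
  }
  ref1 <- emg_process_session(crt)$ref_peak
  ref2 <- emg_process_session(scale_all(crt, 3))$ref_peak
  expect_equal(ref2 / ref1, 3, tolerance = 1e-9)
  p1 <- emg_process_session(sim, ref_peak = ref1)$trials
  p2 <- emg_process_session(scale_all(sim, 3), ref_peak = ref2)$trials
  expect_identical(p1$phenotype, p2$phenotype)
  expect_equal(mean(p1$premg), mean(p2$premg))
})
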