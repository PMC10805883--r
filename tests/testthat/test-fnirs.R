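make_intensity_series <- function(n_t = 400, fs = 7.8125, n_extra = 0,
                                  base = 2) {
  hp <- haemo_sim_params()
  mont <- make_montage(hp)
  data <- array(base, dim = c(nrow(mont), 2, n_t),
                dimnames = list(NULL, c("760", "850"), NULL))
  stopcancel:::new_haemo_series(data, mont, c(760, 850), fs,
                                tibble::tibble(time_s = numeric(),
                                               condition = character(),
                                               outcome = character()),
                                "INTENSITY")
}

test_that("channel pruning drops low-SNR, out-of-range and wide channels", {
  s <- make_intensity_series()
  set.seed(1)
  # channel 1: noisy (SNR ~1.5); channel 2: wide separation; channel 3: dim
  s$data[1, 1, ] <- 2 + rnorm(dim(s$data)[3], 0, 2 / 1.5)
  s$channels$separation_mm[2] <- 50
  s$data[3, , ] <- 0.5
  out <- prune_channels(s)
  expect_setequal(out$removed$channel, c(1, 2, 3))
  expect_equal(dim(out$series$data)[1], dim(s$data)[1] - 3)
  expect_match(out$removed$reason[out$removed$channel == 2], "SDrange")

  # clean 30 mm montage passes untouched
  s2 <- make_intensity_series()
  expect_equal(nrow(prune_channels(s2)$removed), 0)

  s3 <- make_intensity_series()
  s3$data[] <- 0.1
  expect_error(prune_channels(s3), class = "stopcancel_processing_error")
})

test_that("optical density is the mean-relative negative log intensity", {
  s <- make_intensity_series()
  od <- to_optical_density(s)
  expect_equal(max(abs(od$data)), 0)

  s2 <- make_intensity_series()
  set.seed(2)
  v <- exp(rnorm(dim(s2$data)[3], 0, 0.1))
  s2$data[1, 1, ] <- v
  od2 <- to_optical_density(s2)
  expect_equal(od2$data[1, 1, ], -log(v / mean(v)), tolerance = 1e-12)

  # uniform intensity rescaling leaves OD unchanged
  s3 <- make_intensity_series()
  s3$data[1, 1, ] <- v
  s3$data <- s3$data / 2
  expect_equal(to_optical_density(s3)$data, od2$data, tolerance = 1e-12)

  s4 <- make_intensity_series()
  s4$data[5, 2, 10] <- 0
  expect_error(to_optical_density(s4), class = "stopcancel_processing_error")
})

test_that("motion detection flags steps and dilates by the mask window", {
  s <- make_intensity_series(n_t = 600)
  set.seed(3)
  s$data <- s$data * exp(-array(rnorm(length(s$data), 0, 0.003),
                                dim = dim(s$data)))
  od <- to_optical_density(s)
  base_mask <- detect_motion(od)

  od2 <- od
  step_at <- 300
  od2$data[, , step_at:dim(od2$data)[3]] <-
    od2$data[, , step_at:dim(od2$data)[3]] + 150
  mask <- detect_motion(od2)
  expect_true(mask[step_at])
  # dilation: at least t_mask (1 s) on each side of the crossing
  fs <- od$fs
  expect_true(all(mask[(step_at - floor(fs)):(step_at + floor(fs))]))
  run <- rle(mask)
  expect_true(max(run$lengths[run$values]) >= 2 * floor(fs))
})

test_that("PCA motion correction removes confined rank-one artifacts", {
  s <- make_intensity_series(n_t = 900)
  set.seed(4)
  s$data <- s$data * exp(-array(rnorm(length(s$data), 0, 0.002),
                                dim = dim(s$data)))
  od_clean <- to_optical_density(s)

  # empty mask: identity transform
  no_mask <- rep(FALSE, dim(od_clean$data)[3])
  out0 <- pca_motion_correct(od_clean, mask = no_mask)
  expect_identical(out0$od$data, od_clean$data)
  expect_equal(out0$iterations, 0)

  # inject a rank-one artifact (common loading across channels) in a window
  od_dirty <- od_clean
  idx <- 400:470
  loading <- runif(dim(od_clean$data)[1] * 2, 0.5, 1.5)
  art <- outer(loading, sin(seq(0, pi, length.out = length(idx)))) * 0.5
  col <- 0
  for (ch in seq_len(dim(od_clean$data)[1])) for (w in 1:2) {
    col <- col + 1
    od_dirty$data[ch, w, idx] <- od_dirty$data[ch, w, idx] + art[col, ]
  }
  mask <- rep(FALSE, dim(od_clean$data)[3]); mask[idx] <- TRUE
  out <- pca_motion_correct(od_dirty, mask = mask, max_iter = 5)
  expect_lte(out$iterations, 5)
  resid <- out$od$data[, , idx] - od_clean$data[, , idx]
  orig <- od_dirty$data[, , idx] - od_clean$data[, , idx]
  expect_lt(sum(resid^2) / sum(orig^2), 0.03)
  # samples outside the motion segments are never altered
  expect_identical(out$od$data[, , -idx], od_dirty$data[, , -idx])
})

test_that("haemodynamic low-pass attenuates cardiac band and passes slow waves", {
  fs <- 7.8125
  t <- seq(0, 300, by = 1 / fs)
  s <- make_intensity_series(n_t = length(t))
  amp_after <- function(f_hz) {
    od <- to_optical_density(s)
    od$data[1, 1, ] <- sin(2 * pi * f_hz * t)
    out <- lowpass_haemo(od)
    mid <- seq(200, length(t) - 200)
    max(abs(out$data[1, 1, mid]))
  }
  expect_lt(amp_after(1.0), 0.2)      # >80% attenuation at cardiac rate
  expect_gt(amp_after(0.05), 0.95)    # <5% loss for slow haemodynamics

  od <- to_optical_density(s)
  od$data[1, 1, ] <- od$data[1, 1, ] + 0.4
  out <- lowpass_haemo(od)
  expect_equal(mean(out$data[1, 1, 100:2000]), 0.4, tolerance = 1e-6)
})

test_that("Beer-Lambert inversion recovers concentrations exactly", {
  hp <- haemo_sim_params()
  fs <- hp$fs_fnirs
  ev <- data.frame(time_s = 256 / fs, condition = "STOP_SUCCESS",
                   outcome = "success")
  fn <- simulate_fnirs(hp, ev, duration_s = 90, seed = 5, physio = FALSE,
                       noise = FALSE, spikes = FALSE)
  conc <- od_to_concentration(to_optical_density(fn$series))
  # HbT is the species sum at every sample
  expect_equal(conc$data[, "HbT", ],
               conc$data[, "HbO2", ] + conc$data[, "HbR", ],
               tolerance = 1e-12)
  # recovered HbO2 equals the generator truth up to the OD mean offset,
  # which baseline-zeroed epoching removes; compare after centring
  ch1 <- conc$data[1, "HbO2", ] - mean(conc$data[1, "HbO2", ])
  truth <- fn$truth$hbo2[1, ] - mean(fn$truth$hbo2[1, ])
  expect_equal(ch1, truth, tolerance = 1e-10)

  # zero OD gives zero concentration
  od0 <- to_optical_density(make_intensity_series())
  c0 <- od_to_concentration(od0)
  expect_equal(max(abs(c0$data)), 0)

  bad_e <- matrix(c(1, 2, 2, 4), 2, dimnames = list(c("760", "850"),
                                                    c("HbO2", "HbR")))
  expect_error(od_to_concentration(od0, extinction = bad_e),
               class = "stopcancel_config_error")
})

test_that("cross-talk from a pure-HbO2 simulation is bounded", {
  hp <- haemo_sim_params(hbr_ratio = 0)
  fs <- hp$fs_fnirs
  ev <- data.frame(time_s = 256 / fs, condition = "STOP_SUCCESS",
                   outcome = "success")
  fn <- simulate_fnirs(hp, ev, duration_s = 90, seed = 6, physio = FALSE,
                       noise = FALSE, spikes = FALSE)
  conc <- od_to_concentration(to_optical_density(fn$series))
  hbo2_rng <- diff(range(conc$data[1, "HbO2", ]))
  hbr_rng <- diff(range(conc$data[1, "HbR", ]))
  expect_lt(hbr_rng / hbo2_rng, 0.05)
})

test_that("hemisphere averaging excludes midline and tolerates pruning", {
  hp <- haemo_sim_params()
  mont <- make_montage(hp)
  n_t <- 100
  conc <- array(0, dim = c(nrow(mont), 3, n_t),
                dimnames = list(NULL, c("HbO2", "HbR", "HbT"), NULL))
  conc[, 1, ] <- 1  # identical channels
  s <- stopcancel:::new_haemo_series(conc, mont, c(760, 850), hp$fs_fnirs,
                                     tibble::tibble(), "CONC",
                                     c("HbO2", "HbR", "HbT"))
  h <- hemisphere_average(s)
  expect_equal(h$data["LEFT", "HbO2", ], rep(1, n_t))

  # perturbing a midline channel changes nothing
  s2 <- s
  s2$data[which(mont$hemisphere == "MIDLINE")[1], 1, ] <- 99
  expect_equal(hemisphere_average(s2)$data, h$data)

  # dropping one left channel averages the remaining nine
  s3 <- s
  keep <- -which(mont$hemisphere == "LEFT")[1]
  s3$data <- s3$data[keep, , , drop = FALSE]
  s3$channels <- s3$channels[keep, ]
  s3$data[1, 1, ] <- 3  # one remaining LEFT channel off-value
  h3 <- hemisphere_average(s3)
  expect_equal(h3$data["LEFT", "HbO2", 1], (3 + 8 * 1) / 9)

  # a hemisphere with no survivors is reported missing
  s4 <- s
  left <- which(mont$hemisphere == "LEFT")
  s4$data <- s4$data[-left, , , drop = FALSE]
  s4$channels <- s4$channels[-left, ]
  h4 <- hemisphere_average(s4)
  expect_equal(attr(h4, "missing_hemispheres"), "LEFT")
})

test_that("epoching zeroes the baseline and averages within groups", {
  hp <- haemo_sim_params()
  fs <- hp$fs_fnirs
  ev <- data.frame(time_s = c(256, 1792, 3328) / fs,
                   condition = "STOP_SUCCESS", outcome = "success")
  fn <- simulate_fnirs(hp, ev, duration_s = 460, seed = 7, physio = FALSE,
                       noise = FALSE, spikes = FALSE)
  hemi <- hemisphere_average(od_to_concentration(
    to_optical_density(fn$series)))
  out <- epoch_and_average(hemi)
  ep <- out$epochs$epoch[[1]]
  base <- ep$hbo2[ep$time_s < 2]
  expect_lt(abs(mean(base)), 1e-12)
  # identical epochs (well-separated identical events): CI width ~0
  expect_lt(max(ep$hbo2_hi - ep$hbo2_lo), 1e-9)

  # an event too close to the end is dropped with a record
  ev2 <- rbind(ev, data.frame(time_s = 455, condition = "STOP_SUCCESS",
                              outcome = "success"))
  fn2 <- simulate_fnirs(hp, ev2, duration_s = 460, seed = 8,
                        physio = FALSE, noise = FALSE, spikes = FALSE)
  hemi2 <- hemisphere_average(od_to_concentration(
    to_optical_density(fn2$series)))
  out2 <- epoch_and_average(hemi2)
  expect_equal(nrow(out2$dropped), 1)
  expect_equal(out2$epochs$n[1], 3)
})

test_that("peak HbO2 extraction uses the 4-7 s window with inclusive bounds", {
  # monotone decreasing epoch: the peak sits at the 4 s boundary
  tt <- seq(0, 10, by = 0.128)
  ep <- tibble::tibble(time_s = tt, hbo2 = 1 - 0.05 * tt)
  pk <- peak_hbo2(ep)
  expect_equal(pk$peak_time_s, min(tt[tt >= 4]))

  # adding a constant shifts the peak value by exactly that constant
  ep2 <- ep; ep2$hbo2 <- ep2$hbo2 + 0.3
  expect_equal(peak_hbo2(ep2)$peak_umol, pk$peak_umol + 0.3)

  expect_error(peak_hbo2(tibble::tibble(time_s = 0:3, hbo2 = rep(0, 4))),
               class = "stopcancel_processing_error")
})

test_that("the noiseless pipeline is scale-consistent end to end", {
  run_amp <- function(a) {
    hp <- haemo_sim_params(amplitude_by_condition = c(STOP_SUCCESS = a))
    fs <- hp$fs_fnirs
    ev <- data.frame(time_s = 256 / fs, condition = "STOP_SUCCESS",
                     outcome = "success")
    fn <- simulate_fnirs(hp, ev, duration_s = 90, seed = 9, physio = FALSE,
                         noise = FALSE, spikes = FALSE)
    hemi <- hemisphere_average(od_to_concentration(
      to_optical_density(fn$series)))
    ep <- epoch_and_average(hemi)$epochs$epoch[[1]]
    peak_hbo2(ep)$peak_umol
  }
  expect_equal(run_amp(0.8) / run_amp(0.4), 2, tolerance = 1e-12)
})
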