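#' Prune noisy or out-of-range fNIRS channels
#'
#' Drops channels whose mean raw intensity falls outside `d_range`, whose
#' signal-to-noise ratio (mean / SD of raw intensity) is below `snr_thresh`
#' at either wavelength, or whose source-detector separation lies outside
#' `sd_range_mm`.
#'
#' @param series an INTENSITY-domain `haemo_series`.
#' @param d_range admissible mean raw intensity, recorded units.
#' @param snr_thresh minimum mean/SD.
#' @param sd_range_mm admissible source-detector separation.
#' @return List: `series` (pruned) and `removed` (tibble: channel, reason).
#' @export
prune_channels <- function(series, d_range = c(1, 3), snr_thresh = 2,
                           sd_range_mm = c(0, 45)) {
  stopifnot(inherits(series, "haemo_series"), series$domain == "INTENSITY")
  n_ch <- dim(series$data)[1]
  removed <- list()
  keep <- rep(TRUE, n_ch)
  for (ch in seq_len(n_ch)) {
    sep <- series$channels$separation_mm[ch]
    reasons <- character(0)
    if (sep < sd_range_mm[1] || sep > sd_range_mm[2]) {
      reasons <- c(reasons, "separation outside SDrange")
    }
    for (w in seq_along(series$wavelengths)) {
      x <- series$data[ch, w, ]
      m <- mean(x); s <- stats::sd(x)
      if (m < d_range[1] || m > d_range[2]) {
        reasons <- c(reasons, sprintf("mean intensity outside dRange (%dnm)",
                                      series$wavelengths[w]))
      }
      snr <- if (s == 0) Inf else m / s
      if (snr < snr_thresh) {
        reasons <- c(reasons, sprintf("SNR below threshold (%dnm)",
                                      series$wavelengths[w]))
      }
    }
    if (length(reasons)) {
      keep[ch] <- FALSE
      removed[[length(removed) + 1]] <-
        tibble::tibble(channel = series$channels$channel[ch],
                       reason = paste(unique(reasons), collapse = "; "))
    }
  }
  if (!any(keep)) {
    stopc_abort("channel pruning removed every channel",
                "stopcancel_processing_error")
  }
  series$data <- series$data[keep, , , drop = FALSE]
  series$channels <- series$channels[keep, ]
  list(series = series,
       removed = if (length(removed)) dplyr::bind_rows(removed)
                 else tibble::tibble(channel = integer(),
                                     reason = character()))
}

#' Convert raw intensity to optical density
#'
#' `OD(t) = -ln(I(t) / mean_t(I))` per channel and wavelength; the
#' mean-relative definition makes OD invariant to uniform intensity
#' rescaling (source power, coupling).
#'
#' @param series INTENSITY-domain `haemo_series` with strictly positive
#'   samples.
#' @return OD-domain `haemo_series`.
#' @export
to_optical_density <- function(series) {
  stopifnot(inherits(series, "haemo_series"), series$domain == "INTENSITY")
  for (ch in seq_len(dim(series$data)[1])) {
    for (w in seq_along(series$wavelengths)) {
      x <- series$data[ch, w, ]
      if (any(x <= 0)) {
        stopc_abort(sprintf(
          "non-positive intensity in channel %d (%d nm)",
          series$channels$channel[ch], series$wavelengths[w]),
          "stopcancel_processing_error")
      }
      series$data[ch, w, ] <- -log(x / mean(x))
    }
  }
  series$domain <- "OD"
  series
}

#' Flag motion-artifact time points in optical density
#'
#' A sample is flagged when, within any window of `t_motion` seconds
#' covering it on any channel/wavelength, the OD excursion (max minus min)
#' exceeds `stdev_thresh` times that channel's OD-derivative SD, or exceeds
#' `amp_thresh` OD units. Flags are then dilated by `t_mask` seconds on each
#' side.
#'
#' @param od OD-domain `haemo_series`.
#' @param t_motion sliding-window length, s.
#' @param t_mask dilation on each side of a flagged point, s.
#' @param stdev_thresh threshold in derivative SDs.
#' @param amp_thresh absolute OD excursion threshold.
#' @return Logical vector over time (`TRUE` = motion).
#' @export
detect_motion <- function(od, t_motion = 0.5, t_mask = 1,
                          stdev_thresh = 9, amp_thresh = 100) {
  stopifnot(inherits(od, "haemo_series"), od$domain == "OD")
  n_t <- dim(od$data)[3]
  w <- max(2L, as.integer(round(t_motion * od$fs)))
  flag <- rep(FALSE, n_t)
  for (ch in seq_len(dim(od$data)[1])) {
    for (wl in seq_along(od$wavelengths)) {
      x <- od$data[ch, wl, ]
      sd_d <- stats::sd(diff(x))
      thr <- stdev_thresh * sd_d
      # sliding-window range via vectorised running max/min
      shifts <- lapply(0:(w - 1), function(k) x[(1 + k):(n_t - w + 1 + k)])
      rng <- do.call(pmax, shifts) - do.call(pmin, shifts)
      bad <- which(rng > thr | rng > amp_thresh)
      for (s in bad) flag[s:(s + w - 1)] <- TRUE
    }
  }
  if (any(flag)) {
    d <- as.integer(round(t_mask * od$fs))
    idx <- which(flag)
    lo <- pmax(1L, idx - d)
    hi <- pmin(n_t, idx + d)
    for (k in seq_along(idx)) flag[lo[k]:hi[k]] <- TRUE
  }
  flag
}

#' PCA-based correction of motion-contaminated segments
#'
#' Iteratively: gather the flagged samples across all channels and
#' wavelengths, run a principal components analysis on that segment matrix
#' only (so clean data are never altered), remove the smallest leading set
#' of components whose cumulative explained variance reaches `nSV` (97%),
#' reconstruct the flagged samples from the remainder, offset-correct each
#' corrected run so its end points join the neighbouring clean samples, and
#' re-detect motion. Stops when the mask is empty or after `max_iter`
#' iterations.
#'
#' @param od OD-domain `haemo_series`.
#' @param mask logical time mask from [detect_motion()]; `NULL` to detect
#'   internally.
#' @param nSV cumulative variance fraction to remove.
#' @param max_iter iteration cap.
#' @param ... passed on to [detect_motion()] for re-detection.
#' @return List: `od` (corrected series), `iterations`, `final_mask`.
#' @export
pca_motion_correct <- function(od, mask = NULL, nSV = 0.97, max_iter = 5,
                               ...) {
  stopifnot(inherits(od, "haemo_series"), od$domain == "OD")
  if (is.null(mask)) mask <- detect_motion(od, ...)
  n_ch <- dim(od$data)[1]; n_wl <- dim(od$data)[2]; n_t <- dim(od$data)[3]
  iterations <- 0L
  while (any(mask) && iterations < max_iter) {
    iterations <- iterations + 1L
    idx <- which(mask)
    if (length(idx) <= n_ch * n_wl) {
      warning("fewer flagged samples than channels; PCA skipped")
      break
    }
    # time x (channel*wavelength) matrix of flagged samples
    m <- matrix(NA_real_, nrow = length(idx), ncol = n_ch * n_wl)
    col <- 0L
    for (ch in seq_len(n_ch)) for (wl in seq_len(n_wl)) {
      col <- col + 1L
      m[, col] <- od$data[ch, wl, idx]
    }
    # uncentered SVD: removal is then a pure projection, so samples inside
    # the mask that carry no artifact are nearly untouched
    sv <- svd(m)
    var_expl <- sv$d^2 / sum(sv$d^2)
    k <- which(cumsum(var_expl) >= nSV)[1]
    if (is.na(k)) k <- length(sv$d)
    # reconstruct without the leading k components
    keep <- seq_along(sv$d) > k
    recon <- sv$u[, keep, drop = FALSE] %*%
      (diag(sv$d[keep], nrow = sum(keep)) %*%
         t(sv$v[, keep, drop = FALSE]))
    col <- 0L
    for (ch in seq_len(n_ch)) for (wl in seq_len(n_wl)) {
      col <- col + 1L
      x <- od$data[ch, wl, ]
      x[idx] <- recon[, col]
      # stitch each corrected run to its clean neighbours with a linear ramp
      runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
      for (r in runs) {
        a <- r[1]; b <- r[length(r)]
        left <- if (a > 1) x[a - 1] else x[a]
        right <- if (b < n_t) x[b + 1] else x[b]
        d_start <- left - x[a]
        d_end <- right - x[b]
        ramp <- seq(d_start, d_end, length.out = length(r))
        x[r] <- x[r] + ramp
      }
      od$data[ch, wl, ] <- x
    }
    mask <- detect_motion(od, ...)
  }
  list(od = od, iterations = iterations, final_mask = mask)
}

#' Zero-phase low-pass filter for haemodynamic series
#'
#' Third-order Butterworth at 0.5 Hz (forward-backward) removing cardiac
#' and most respiratory power while passing the haemodynamic band.
#'
#' @param od OD- (or CONC-) domain `haemo_series`.
#' @param cutoff_hz cutoff frequency.
#' @param order filter order.
#' @return Filtered series.
#' @export
lowpass_haemo <- function(od, cutoff_hz = 0.5, order = 3) {
  stopifnot(inherits(od, "haemo_series"))
  nyq <- od$fs / 2
  stopifnot(cutoff_hz > 0, cutoff_hz < nyq)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  for (ch in seq_len(dim(od$data)[1])) {
    for (w in seq_len(dim(od$data)[2])) {
      od$data[ch, w, ] <- as.numeric(signal::filtfilt(bf, od$data[ch, w, ]))
    }
  }
  od
}

#' Optical density to haemoglobin concentrations (modified Beer-Lambert)
#'
#' Inverts the two-wavelength modified Beer-Lambert law per channel:
#' `c = 1e6 * E^-1 %*% (dOD / (d_cm * DPF))` giving HbO2 and HbR changes in
#' umol, with HbT = HbO2 + HbR appended. The extinction table defaults to
#' the same shared constants the forward simulator uses.
#'
#' @param od OD-domain `haemo_series`.
#' @param dpf named differential pathlength factors per wavelength.
#' @param extinction 2x2 extinction matrix (wavelength x species).
#' @return CONC-domain `haemo_series`: data is channel x species x time
#'   with species `HbO2`, `HbR`, `HbT`.
#' @export
od_to_concentration <- function(od, dpf = default_dpf(),
                                extinction = extinction_coefficients()) {
  stopifnot(inherits(od, "haemo_series"), od$domain == "OD")
  if (abs(det(extinction)) < 1e-9) {
    stopc_abort("extinction matrix is singular",
                "stopcancel_config_error")
  }
  e_inv <- solve(extinction)
  n_ch <- dim(od$data)[1]; n_t <- dim(od$data)[3]
  conc <- array(NA_real_, dim = c(n_ch, 3, n_t),
                dimnames = list(NULL, c("HbO2", "HbR", "HbT"), NULL))
  wl_key <- as.character(od$wavelengths)
  for (ch in seq_len(n_ch)) {
    d_cm <- od$channels$separation_mm[ch] / 10
    scaled <- rbind(od$data[ch, 1, ] / (d_cm * dpf[[wl_key[1]]]),
                    od$data[ch, 2, ] / (d_cm * dpf[[wl_key[2]]]))
    hb <- 1e6 * (e_inv %*% scaled)
    conc[ch, "HbO2", ] <- hb[1, ]
    conc[ch, "HbR", ] <- hb[2, ]
    conc[ch, "HbT", ] <- hb[1, ] + hb[2, ]
  }
  out <- new_haemo_series(conc, od$channels, od$wavelengths, od$fs,
                          od$events, "CONC",
                          species = c("HbO2", "HbR", "HbT"))
  out
}

#' Average concentration series within hemispheres
#'
#' Unweighted mean over surviving non-midline channels, separately for the
#' left and right prefrontal cortex; midline channels are excluded.
#'
#' @param conc CONC-domain `haemo_series`.
#' @return CONC-domain `haemo_series` with one "channel" per hemisphere
#'   (attribute `missing_hemispheres` lists hemispheres with no surviving
#'   channel).
#' @export
hemisphere_average <- function(conc) {
  stopifnot(inherits(conc, "haemo_series"), conc$domain == "CONC")
  hemis <- c("LEFT", "RIGHT")
  n_t <- dim(conc$data)[3]
  data <- array(NA_real_, dim = c(2, 3, n_t),
                dimnames = list(hemis, dimnames(conc$data)[[2]], NULL))
  missing <- character(0)
  for (h in seq_along(hemis)) {
    sel <- which(conc$channels$hemisphere == hemis[h])
    if (length(sel) == 0) {
      missing <- c(missing, hemis[h])
      next
    }
    for (sp in 1:3) {
      block <- conc$data[sel, sp, , drop = FALSE]
      data[h, sp, ] <- colMeans(matrix(block, nrow = length(sel)))
    }
  }
  channels <- tibble::tibble(channel = 1:2, source = NA_integer_,
                             detector = NA_integer_, hemisphere = hemis,
                             separation_mm = NA_real_)
  out <- new_haemo_series(data, channels, conc$wavelengths, conc$fs,
                          conc$events, "CONC", species = conc$species)
  attr(out, "missing_hemispheres") <- missing
  out
}

#' Extract and average stimulus-locked haemodynamic epochs
#'
#' Per event: a `[0, 10]` s window phase-locked to stimulus onset is cut
#' from each channel, zeroed on its `[0, 2]` s baseline mean, grouped by
#' `(condition, outcome)` and averaged with a pointwise 95% confidence
#' interval. Events closer than the window length to the end of the
#' recording are dropped (and reported).
#'
#' @param conc CONC-domain `haemo_series` (typically hemisphere-averaged);
#'   its `events` table needs `time_s`, `condition` and optionally
#'   `outcome`.
#' @param window_s epoch window after onset, s.
#' @param baseline_s baseline-zeroing window, s.
#' @return List: `epochs` (tibble: channel/hemisphere label, condition,
#'   outcome, n, and a list-column `epoch` of tibbles time_s x species mean
#'   and CI), `dropped` (tibble of skipped events).
#' @export
epoch_and_average <- function(conc, window_s = c(0, 10),
                              baseline_s = c(0, 2)) {
  stopifnot(inherits(conc, "haemo_series"), conc$domain == "CONC")
  ev <- tibble::as_tibble(conc$events)
  if (!"outcome" %in% names(ev)) ev$outcome <- NA_character_
  fs <- conc$fs
  n_t <- dim(conc$data)[3]
  n_win <- as.integer(floor((window_s[2] - window_s[1]) * fs)) + 1L
  rel_t <- window_s[1] + (seq_len(n_win) - 1) / fs
  base_sel <- rel_t >= baseline_s[1] & rel_t < baseline_s[2]

  start_idx <- as.integer(round(ev$time_s * fs)) + 1L
  ok <- start_idx + n_win - 1L <= n_t & start_idx >= 1L
  dropped <- ev[!ok, ]
  ev <- ev[ok, ]
  start_idx <- start_idx[ok]
  if (nrow(ev) == 0) {
    stopc_abort("no events with a complete epoch window",
                "stopcancel_processing_error")
  }

  labels <- conc$channels$hemisphere
  groups <- unique(ev[, c("condition", "outcome")])
  rows <- list()
  for (ch in seq_len(dim(conc$data)[1])) {
    for (g in seq_len(nrow(groups))) {
      sel <- which(ev$condition == groups$condition[g] &
                     (ev$outcome %in% groups$outcome[g] |
                        (is.na(ev$outcome) & is.na(groups$outcome[g]))))
      if (length(sel) == 0) next
      cube <- array(NA_real_, dim = c(length(sel), 3, n_win))
      for (k in seq_along(sel)) {
        i0 <- start_idx[sel[k]]
        seg <- conc$data[ch, , i0:(i0 + n_win - 1L)]
        seg <- seg - rowMeans(seg[, base_sel, drop = FALSE])
        cube[k, , ] <- seg
      }
      n <- length(sel)
      mu <- apply(cube, c(2, 3), mean)
      s <- if (n > 1) apply(cube, c(2, 3), stats::sd) else mu * 0
      half <- if (n > 1) qt(0.975, df = n - 1) * s / sqrt(n) else s
      epoch <- tibble::tibble(
        time_s = rel_t,
        hbo2 = mu[1, ], hbr = mu[2, ], hbt = mu[3, ],
        hbo2_lo = mu[1, ] - half[1, ], hbo2_hi = mu[1, ] + half[1, ])
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = labels[ch], condition = groups$condition[g],
        outcome = groups$outcome[g], n = n, epoch = list(epoch))
    }
  }
  list(epochs = dplyr::bind_rows(rows), dropped = dropped)
}

#' Peak oxyhaemoglobin change within the response window
#'
#' Signed maximum of the baseline-zeroed HbO2 epoch within 4--7 s after
#' stimulus onset (inclusive bounds), the standard event-related activation
#' metric for slow haemodynamic responses.
#'
#' @param epoch one epoch tibble (`time_s`, `hbo2`), as stored by
#'   [epoch_and_average()].
#' @param window_s search window, s.
#' @return List: `peak_umol`, `peak_time_s`.
#' @export
peak_hbo2 <- function(epoch, window_s = c(4, 7)) {
  sel <- epoch$time_s >= window_s[1] & epoch$time_s <= window_s[2]
  if (!any(sel)) {
    stopc_abort("epoch does not span the peak window",
                "stopcancel_processing_error")
  }
  y <- epoch$hbo2[sel]; tt <- epoch$time_s[sel]
  i <- which.max(y)
  list(peak_umol = y[i], peak_time_s = tt[i])
}
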