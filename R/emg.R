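#' Construct an EMG trace
#'
#' Light container for one trial's single-channel surface EMG. Times follow
#' one convention package-wide: milliseconds relative to go-signal onset
#' (t = 0), with the stop signal at t = SSD.
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling rate, Hz (2000 by acquisition convention).
#' @param t0_s time of the first sample relative to the go signal, seconds
#'   (negative for pre-go baseline).
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param trial_id optional identifier.
#' @return An `emg_trace`.
#' @export
emg_trace <- function(samples, fs = 2000, t0_s = 0, side = NA_character_,
                      trial_id = NA) {
  if (!all(is.finite(samples))) {
    stopc_abort("EMG samples must be finite", "stopcancel_invalid_parameter")
  }
  stopifnot(fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, t0_s = t0_s,
                 side = side, trial_id = trial_id), class = "emg_trace")
}

trace_time_ms <- function(trace) {
  (trace$t0_s + (seq_along(trace$samples) - 1) / trace$fs) * 1000
}

#' Zero-phase Butterworth band-pass filter for EMG
#'
#' Fourth-order Butterworth between 20 and 500 Hz, applied forward and
#' backward (`signal::filtfilt`) so that burst onsets and peaks are not
#' delayed by filter group delay.
#'
#' @param trace an [emg_trace()].
#' @param lo,hi band edges, Hz; must satisfy `lo < hi < fs/2`.
#' @param order filter order.
#' @return The filtered `emg_trace` (same length).
#' @export
emg_bandpass <- function(trace, lo = 20, hi = 500, order = 4) {
  stopifnot(inherits(trace, "emg_trace"))
  nyq <- trace$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stopc_abort(sprintf(
      "band edges must satisfy 0 < lo < hi < fs/2 (= %g Hz)", nyq),
      "stopcancel_invalid_parameter")
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  trace$samples <- as.numeric(signal::filtfilt(bf, trace$samples))
  trace
}

#' Rectified low-passed EMG envelope
#'
#' Full-wave rectification followed by a zero-phase low-pass at 10 Hz gives
#' the smooth activation profile used for burst detection, prEMG
#' classification and Cancel Time. Negative filter ripple is clipped to 0.
#'
#' @param trace a band-passed [emg_trace()].
#' @param lp low-pass cutoff, Hz.
#' @param order filter order.
#' @return The envelope as an `emg_trace` (non-negative samples).
#' @export
emg_envelope <- function(trace, lp = 10, order = 4) {
  stopifnot(inherits(trace, "emg_trace"))
  nyq <- trace$fs / 2
  stopifnot(lp > 0, lp < nyq)
  bf <- signal::butter(order, lp / nyq, type = "low")
  env <- as.numeric(signal::filtfilt(bf, abs(trace$samples)))
  trace$samples <- pmax(env, 0)
  trace
}

# Baseline = the quietest `baseline_ms` window of the envelope (window with
# minimal mean activity); returns its mean and SD.
quietest_baseline <- function(env, fs, baseline_ms) {
  w <- as.integer(round(baseline_ms / 1000 * fs))
  n <- length(env)
  if (w < 2 || n < w) {
    stopc_abort("trial shorter than the baseline window",
                "stopcancel_processing_error")
  }
  cs <- cumsum(c(0, env))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  start <- which.min(means)
  win <- env[start:(start + w - 1)]
  list(mean = mean(win), sd = stats::sd(win))
}

#' Detect EMG bursts with a single-threshold algorithm
#'
#' The envelope is thresholded at `baseline mean + k * baseline SD`, where
#' the baseline is the quietest `baseline_ms` window within the trial.
#' Supra-threshold runs become bursts; bursts separated by less than
#' `merge_ms` are merged; each burst's peak is the envelope argmax inside
#' it (earliest sample on ties). Threshold crossings are resolved at the
#' sample level only.
#'
#' @param env an envelope `emg_trace` (see [emg_envelope()]).
#' @param k threshold in baseline standard deviations.
#' @param merge_ms merge bursts separated by gaps strictly shorter than
#'   this (ms).
#' @param baseline_ms length of the sliding baseline window (ms).
#' @return Tibble of bursts: `onset_ms`, `offset_ms`, `peak_ms`, `peak_amp`
#'   (zero rows if nothing crosses threshold).
#' @export
detect_bursts <- function(env, k = 3, merge_ms = 20, baseline_ms = 100) {
  stopifnot(inherits(env, "emg_trace"))
  x <- env$samples
  base <- quietest_baseline(x, env$fs, baseline_ms)
  thr <- base$mean + k * base$sd
  above <- x > thr
  if (!any(above)) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          peak_ms = numeric(), peak_amp = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs whose gap is < merge_ms
  gap_samp <- merge_ms / 1000 * env$fs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < gap_samp) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  t_ms <- trace_time_ms(env)
  out <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    pk <- s + which.max(x[s:e]) - 1L
    tibble::tibble(onset_ms = t_ms[s], offset_ms = t_ms[e],
                   peak_ms = t_ms[pk], peak_amp = x[pk])
  })
  dplyr::bind_rows(out)
}

#' Select the response-generating (RT) burst
#'
#' The burst treated as causing the button press: the *last* burst whose
#' onset falls after the go signal and at least `margin_ms` (50 ms) before
#' the press.
#'
#' @param bursts burst table from [detect_bursts()].
#' @param press_ms button-press time, ms after go onset.
#' @param go_ms go-signal time (0 by the package time convention).
#' @param margin_ms minimum onset-to-press lead for a causal link.
#' @return One-row tibble, or `NULL` if no burst qualifies.
#' @export
select_rt_burst <- function(bursts, press_ms, go_ms = 0, margin_ms = 50) {
  if (is.null(bursts) || nrow(bursts) == 0 || is.na(press_ms)) return(NULL)
  ok <- bursts$onset_ms > go_ms & bursts$onset_ms <= press_ms - margin_ms
  if (!any(ok)) return(NULL)
  cand <- bursts[ok, ]
  cand[which.max(cand$onset_ms), ]
}

#' Classify a partial EMG (prEMG) response on a stop trial
#'
#' A successful stop trial carries a prEMG event when some burst (the latest
#' such burst, if several) satisfies all three criteria: (i) onset after the
#' go signal; (ii) envelope peak after the stop signal (so the inhibition
#' was a response to the stop cue); (iii) peak amplitude above `amp_frac`
#' (10%) of the participant's mean response-burst peak from successful CRT
#' go trials. Trials with a button press are failed stops, never prEMG.
#'
#' @param bursts burst table from [detect_bursts()].
#' @param ssd_ms the trial's stop-signal delay, ms.
#' @param press_occurred did a button press occur?
#' @param ref_peak reference peak amplitude (mean CRT response-burst peak);
#'   must be positive.
#' @param amp_frac amplitude criterion as a fraction of `ref_peak`.
#' @param go_ms go-signal time, ms.
#' @return One-row tibble (`onset_ms`, `offset_ms`, `peak_ms`, `peak_amp`,
#'   `ssd_ms`, `cancel_time_ms`, `peak_amp_norm`) or `NULL`.
#' @export
detect_premg <- function(bursts, ssd_ms, press_occurred, ref_peak,
                         amp_frac = 0.10, go_ms = 0) {
  if (!is.finite(ref_peak) || ref_peak <= 0) {
    stopc_abort("prEMG reference peak must be positive",
                "stopcancel_invalid_reference")
  }
  if (isTRUE(press_occurred)) return(NULL)
  if (is.null(bursts) || nrow(bursts) == 0) return(NULL)
  ok <- bursts$onset_ms > go_ms &
    bursts$peak_ms > ssd_ms &
    bursts$peak_amp > amp_frac * ref_peak
  if (!any(ok)) return(NULL)
  ev <- bursts[ok, ][which.max(bursts$onset_ms[ok]), ]
  ev$ssd_ms <- ssd_ms
  ev$cancel_time_ms <- cancel_time(ev, ssd_ms)
  ev$peak_amp_norm <- ev$peak_amp / ref_peak
  ev
}

#' Cancel Time of a prEMG burst
#'
#' The trial-level physiological stopping latency: time from stop-signal
#' onset (SSD) to the peak of the partial-burst envelope. Defined only for
#' bursts whose peak follows the stop signal.
#'
#' @param burst one burst row (needs `peak_ms`).
#' @param ssd_ms stop-signal delay, ms.
#' @return Cancel Time in ms (strictly positive).
#' @export
cancel_time <- function(burst, ssd_ms) {
  ct <- burst$peak_ms - ssd_ms
  if (any(ct <= 0)) {
    stopc_abort("burst peak precedes the stop signal; not a prEMG burst",
                "stopcancel_contract_violation")
  }
  ct
}

#' Normalise EMG envelopes to the CRT reference peak
#'
#' Scales every envelope by the participant's mean response-burst peak
#' amplitude over successful CRT go trials, making profiles comparable
#' across conditions and participants (the mean normalised CRT peak is 1 by
#' construction).
#'
#' @param envelopes list of envelope `emg_trace`s (or numeric vectors).
#' @param reference_peaks numeric vector of CRT response-burst peak
#'   amplitudes (one per successful CRT go trial).
#' @return List with `envelopes` (normalised, same shapes) and `reference`
#'   (the scalar mean peak).
#' @export
normalise_profiles <- function(envelopes, reference_peaks) {
  if (length(reference_peaks) == 0 || !all(is.finite(reference_peaks))) {
    stopc_abort("no CRT reference trials to normalise against",
                "stopcancel_processing_error")
  }
  ref <- mean(reference_peaks)
  if (ref <= 0) {
    stopc_abort("CRT reference peak must be positive",
                "stopcancel_processing_error")
  }
  norm1 <- function(e) {
    if (inherits(e, "emg_trace")) {
      e$samples <- e$samples / ref
      e
    } else e / ref
  }
  list(envelopes = lapply(envelopes, norm1), reference = ref)
}

#' Mean EMG profile with pointwise confidence band
#'
#' Aligns per-trial envelopes either to the stop-signal onset
#' (`align = "STOP_SIGNAL"`, alignment times = SSDs) or to each trial's
#' envelope peak (`align = "PEAK"`), restricts to the common aligned time
#' span, and averages pointwise with a 95% confidence interval.
#'
#' @param envelopes list of envelope `emg_trace`s (common sampling rate).
#' @param align_ms numeric vector of per-trial alignment times (ms relative
#'   to the go signal): SSDs for stop-signal alignment, peak times for peak
#'   alignment.
#' @param align label recorded in the output attribute.
#' @return Tibble: `time_ms` (0 at the alignment event), `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
mean_profile <- function(envelopes, align_ms,
                         align = c("STOP_SIGNAL", "PEAK")) {
  align <- match.arg(align)
  if (length(envelopes) < 2 || length(align_ms) != length(envelopes)) {
    stopc_abort("need >= 2 envelopes with one alignment time each",
                "stopcancel_processing_error")
  }
  fs <- envelopes[[1]]$fs
  rel <- lapply(seq_along(envelopes), function(i) {
    tm <- trace_time_ms(envelopes[[i]]) - align_ms[i]
    list(t = tm, y = envelopes[[i]]$samples)
  })
  lo <- max(vapply(rel, function(r) min(r$t), numeric(1)))
  hi <- min(vapply(rel, function(r) max(r$t), numeric(1)))
  if (hi <= lo) {
    stopc_abort("aligned envelopes share no common time span",
                "stopcancel_processing_error")
  }
  grid <- seq(lo, hi, by = 1000 / fs)
  mat <- vapply(rel, function(r) stats::approx(r$t, r$y, xout = grid)$y,
                numeric(length(grid)))
  n <- length(envelopes)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  half <- qt(0.975, df = n - 1) * s / sqrt(n)
  structure(tibble::tibble(time_ms = grid, mean = mu,
                           ci_lo = mu - half, ci_hi = mu + half, n = n),
            align = align)
}

#' Process all EMG traces of a simulated or recorded session
#'
#' Runs the full per-trial chain (band-pass, envelope, burst detection) on
#' the responding hand's trace, selects response-generating bursts on go
#' trials, classifies stop trials into `FULL_PRESS` / `PARTIAL` / `NO_EMG`,
#' and computes Cancel Times for prEMG events. The amplitude criterion for
#' prEMG needs a CRT reference: supply `ref_peak` (e.g. from a processed CRT
#' session via [crt_reference_peak()]), or let the function derive it when
#' the session itself contains CRT trials.
#'
#' @param sim a `sim_session` (see [simulate_session()]), or a compatible
#'   list with `trials`, `traces`, `fs`, `t0_s`.
#' @param ref_peak CRT reference peak amplitude; `NULL` to derive from CRT
#'   trials in `sim`.
#' @param amp_frac prEMG amplitude criterion fraction.
#' @param keep_envelopes retain per-trial envelopes (memory-heavy).
#' @return List: `trials` (input behaviour plus `phenotype`,
#'   `emg_onset_ms`, `emg_peak_ms`, `emg_peak_amp`, `cancel_time_ms`,
#'   `peak_amp_norm`, `premg`), `ref_peak`, and optionally `envelopes`.
#' @export
emg_process_session <- function(sim, ref_peak = NULL, amp_frac = 0.10,
                                keep_envelopes = FALSE) {
  trials <- sim$trials
  n <- nrow(trials)
  stopifnot(length(sim$traces) == n)

  env_of <- function(i, side) {
    tr <- emg_trace(sim$traces[[i]][, side], fs = sim$fs, t0_s = sim$t0_s,
                    side = side, trial_id = trials$trial_index[i])
    emg_envelope(emg_bandpass(tr))
  }

  analysed_side <- ifelse(!is.na(trials$resp_hand), trials$resp_hand,
                          trials$hand)

  envs <- vector("list", n)
  bursts <- vector("list", n)
  for (i in seq_len(n)) {
    e <- env_of(i, analysed_side[i])
    bursts[[i]] <- detect_bursts(e)
    if (keep_envelopes) envs[[i]] <- e
  }

  rt_burst <- lapply(seq_len(n), function(i) {
    if (!isTRUE(trials$responded[i])) return(NULL)
    select_rt_burst(bursts[[i]], press_ms = trials$rt_ms[i])
  })

  if (is.null(ref_peak)) {
    is_ref <- !trials$practice & trials$condition == "CRT" &
      !trials$is_stop & trials$responded & trials$correct_choice %in% TRUE
    peaks <- vapply(which(is_ref), function(i) {
      b <- rt_burst[[i]]
      if (is.null(b)) NA_real_ else b$peak_amp
    }, numeric(1))
    peaks <- peaks[is.finite(peaks)]
    if (length(peaks) == 0) {
      stopc_abort("no successful CRT go trials to build the prEMG reference",
                  "stopcancel_processing_error")
    }
    ref_peak <- mean(peaks)
  }

  phenotype <- rep(NA_character_, n)
  cancel <- rep(NA_real_, n)
  amp_norm <- rep(NA_real_, n)
  onset <- rep(NA_real_, n)
  peak_ms <- rep(NA_real_, n)
  peak_amp <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    if (trials$is_stop[i]) {
      if (isTRUE(trials$responded[i])) {
        phenotype[i] <- "FULL_PRESS"
        b <- rt_burst[[i]]
        if (!is.null(b)) {
          onset[i] <- b$onset_ms; peak_ms[i] <- b$peak_ms
          peak_amp[i] <- b$peak_amp
        }
      } else {
        ev <- detect_premg(bursts[[i]], trials$ssd_ms[i],
                           press_occurred = FALSE, ref_peak = ref_peak,
                           amp_frac = amp_frac)
        if (is.null(ev)) {
          phenotype[i] <- "NO_EMG"
        } else {
          phenotype[i] <- "PARTIAL"
          cancel[i] <- ev$cancel_time_ms
          amp_norm[i] <- ev$peak_amp_norm
          onset[i] <- ev$onset_ms; peak_ms[i] <- ev$peak_ms
          peak_amp[i] <- ev$peak_amp
        }
      }
    } else if (isTRUE(trials$responded[i])) {
      b <- rt_burst[[i]]
      if (!is.null(b)) {
        onset[i] <- b$onset_ms; peak_ms[i] <- b$peak_ms
        peak_amp[i] <- b$peak_amp
      }
    }
  }

  trials$phenotype <- phenotype
  trials$emg_onset_ms <- onset
  trials$emg_peak_ms <- peak_ms
  trials$emg_peak_amp <- peak_amp
  trials$cancel_time_ms <- cancel
  trials$peak_amp_norm <- amp_norm
  trials$premg <- !is.na(phenotype) & phenotype == "PARTIAL"

  out <- list(trials = trials, ref_peak = ref_peak)
  if (keep_envelopes) out$envelopes <- envs
  out
}

#' Mean response-burst peak from a processed CRT session
#'
#' @param processed output of [emg_process_session()] on a CRT session.
#' @return Scalar reference amplitude.
#' @export
crt_reference_peak <- function(processed) {
  processed$ref_peak
}
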