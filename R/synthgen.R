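#' Horse-race generator parameters
#'
#' Bundles every parameter of the synthetic behaviour/EMG generator. Go RTs
#' are ex-Gaussian (Gaussian mu/sigma plus exponential tau, the standard RT
#' model); an independent stop process of latency `stop_latency_ms` races the
#' go process on stop trials; successful stops whose muscle activation had
#' already begun leave a partial EMG burst whose envelope peaks
#' `cancel_peak_latency_ms` after the stop signal (the trial-level Cancel
#' Time ground truth).
#'
#' Defaults describe a young-adult-like subject: ex-Gaussian go RT
#' (mu 300, sigma 40, tau 80 ms), stop-process latency 190 ms (sd 30),
#' cancellation peak 155 ms after the stop signal (sd 20), EMG onset
#' preceding the button press by 130 ms. These joint choices place the
#' prevalence of partial-EMG stop trials in the empirically reported range
#' (roughly a quarter to a third of stop trials) while keeping the
#' integration SSRT strictly above the mean Cancel Time. An older-adult
#' preset is available via `age_group = "older"` (mu 360, sigma 50,
#' tau 110, slower stopping and cancellation).
#'
#' @param age_group `"young"` or `"older"` preset for the RT/stopping
#'   parameters; individual arguments override the preset.
#' @param go_mu,go_sigma,go_tau ex-Gaussian go RT parameters (ms).
#' @param stop_latency_ms,stop_latency_sd_ms mean and trial-to-trial sd of
#'   the stop-process duration (ms); the integration-method SSRT recovers
#'   the mean.
#' @param cancel_peak_latency_ms,cancel_jitter_sd_ms mean and sd of the true
#'   time from stop-signal onset to the partial-burst envelope peak (ms).
#' @param emg_onset_to_press_ms electromechanical lag from EMG burst onset to
#'   the registered button press (ms).
#' @param burst_amp peak burst amplitude in generator units.
#' @param burst_rise_ms time from burst onset to envelope peak on
#'   response-generating bursts (ms).
#' @param burst_fall_ms Gaussian width (sd, ms) of the response-burst
#'   envelope.
#' @param partial_width_ms Gaussian width (sd, ms) of the partial-burst
#'   envelope about its truncation peak.
#' @param noise_sd baseline EMG noise standard deviation (generator units).
#' @param fs_emg EMG sampling rate, Hz.
#' @param proactive_slow_ms additive go slowing applied in stop-expectation
#'   contexts (SST/SSFT); 0 encodes context independence.
#' @param flanker_effect_ms named additive RT shifts per congruency level
#'   (`CONGRUENT`, `INCONGRUENT`, `NEUTRAL`); `NONE` always maps to 0.
#' @param go_omission_rate probability a go process is never initiated
#'   (attentional lapse: no press, no EMG).
#' @param choice_error_rate probability the wrong hand responds.
#' @param deadline_ms response deadline; slower go processes register no
#'   press.
#' @param trace_pre_s,trace_post_s EMG trace extent around the go signal (s).
#' @return A `race_params` list.
#' @export
race_params <- function(age_group = c("young", "older"),
                        go_mu = NULL, go_sigma = NULL, go_tau = NULL,
                        stop_latency_ms = NULL, stop_latency_sd_ms = 30,
                        cancel_peak_latency_ms = NULL,
                        cancel_jitter_sd_ms = 20,
                        emg_onset_to_press_ms = 130,
                        burst_amp = 1, burst_rise_ms = 120,
                        burst_fall_ms = 45, partial_width_ms = 40,
                        noise_sd = 0.05, fs_emg = 2000,
                        proactive_slow_ms = 0,
                        flanker_effect_ms = c(CONGRUENT = 0, INCONGRUENT = 57,
                                              NEUTRAL = 0),
                        go_omission_rate = 0.01, choice_error_rate = 0.02,
                        deadline_ms = 1500,
                        trace_pre_s = 0.2, trace_post_s = 1.6) {
  age_group <- match.arg(age_group)
  flanker_effect_ms <- unlist(flanker_effect_ms)
  preset <- if (age_group == "young") {
    list(go_mu = 300, go_sigma = 40, go_tau = 80,
         stop_latency_ms = 190, cancel_peak_latency_ms = 155)
  } else {
    list(go_mu = 360, go_sigma = 50, go_tau = 110,
         stop_latency_ms = 250, cancel_peak_latency_ms = 208)
  }
  p <- list(
    age_group = age_group,
    go_mu = go_mu %||% preset$go_mu,
    go_sigma = go_sigma %||% preset$go_sigma,
    go_tau = go_tau %||% preset$go_tau,
    stop_latency_ms = stop_latency_ms %||% preset$stop_latency_ms,
    stop_latency_sd_ms = stop_latency_sd_ms,
    cancel_peak_latency_ms =
      cancel_peak_latency_ms %||% preset$cancel_peak_latency_ms,
    cancel_jitter_sd_ms = cancel_jitter_sd_ms,
    emg_onset_to_press_ms = emg_onset_to_press_ms,
    burst_amp = burst_amp, burst_rise_ms = burst_rise_ms,
    burst_fall_ms = burst_fall_ms, partial_width_ms = partial_width_ms,
    noise_sd = noise_sd, fs_emg = fs_emg,
    proactive_slow_ms = proactive_slow_ms,
    flanker_effect_ms = flanker_effect_ms,
    go_omission_rate = go_omission_rate,
    choice_error_rate = choice_error_rate,
    deadline_ms = deadline_ms,
    trace_pre_s = trace_pre_s, trace_post_s = trace_post_s
  )
  stopifnot(p$go_sigma > 0, p$go_tau > 0, p$stop_latency_ms > 0,
            p$cancel_peak_latency_ms > 0, p$emg_onset_to_press_ms > 0,
            p$noise_sd > 0, p$fs_emg > 0)
  structure(p, class = "race_params")
}

rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

flanker_shift <- function(params, congruency) {
  if (congruency == "NONE") return(0)
  unname(params$flanker_effect_ms[congruency] %||% 0)
}

# Burst envelope: a Gaussian bump gated sharply at onset so detected onsets
# track truth. Times in ms relative to the go signal; `t` is the trace time
# axis. Partial bursts use a symmetric Gaussian about the truncation peak so
# that downstream 10 Hz envelope smoothing does not bias the peak-time
# estimate.
burst_envelope <- function(t_ms, onset_ms, peak_ms, width_ms, gate_ms = 3) {
  tau <- t_ms - onset_ms
  env <- numeric(length(t_ms))
  on <- tau > 0
  env[on] <- (1 - exp(-tau[on] / gate_ms)) *
    exp(-((t_ms[on] - peak_ms)^2) / (2 * width_ms^2))
  env
}

emg_trace_axis <- function(params) {
  n <- as.integer(round((params$trace_pre_s + params$trace_post_s) *
                          params$fs_emg))
  t0 <- -params$trace_pre_s
  list(t_ms = (t0 + (seq_len(n) - 1) / params$fs_emg) * 1000, t0 = t0, n = n)
}

synth_trace <- function(params, env_amp) {
  n <- length(env_amp)
  params$noise_sd * rnorm(n) + env_amp * rnorm(n)
}

#' Simulate one trial of the horse-race model
#'
#' Draws a go process, races it against the stop process on stop trials, and
#' synthesises the bipolar EMG traces for both hands. On stop trials the
#' outcome phenotype is one of `FULL_PRESS` (go wins: a failed stop with a
#' button press), `PARTIAL` (stop wins but muscle activation had begun: a
#' burst truncated so its envelope peaks `cancel_peak_latency_ms` after the
#' stop signal), or `NO_EMG` (stop cancelled the response before any muscle
#' activation).
#'
#' @param params a [race_params()].
#' @param condition,congruency,hand,is_stop trial attributes (see
#'   [generate_session()]).
#' @param ssd_ms stop-signal delay for this trial (ms); ignored on go trials.
#' @param emg if `FALSE`, skip trace synthesis (behaviour + truth only).
#' @return A list with `behaviour` (one-row tibble: rt_ms, responded,
#'   resp_hand, correct_choice, go_omission), `truth` (one-row tibble:
#'   true_go_rt_ms, true_stop_wins, true_phenotype, true_cancel_peak_ms,
#'   true_onset_ms, true_peak_ms, true_amp) and `trace` (samples x 2 matrix,
#'   columns LEFT/RIGHT, or `NULL`).
#' @export
simulate_trial <- function(params, condition, congruency, hand,
                           is_stop = FALSE, ssd_ms = NA_real_, emg = TRUE) {
  stopifnot(inherits(params, "race_params"))
  proactive <- if (condition %in% c("SST", "SSFT")) params$proactive_slow_ms else 0
  lapse <- runif(1) < params$go_omission_rate
  g <- rexgauss(1, params$go_mu, params$go_sigma, params$go_tau) +
    flanker_shift(params, congruency) + proactive
  delay <- params$emg_onset_to_press_ms
  onset <- g - delay

  phenotype <- NA_character_
  press <- NA_real_
  cancel_peak <- NA_real_
  peak_ms <- NA_real_
  amp <- 0
  stop_wins <- NA

  if (!is_stop || is.na(ssd_ms)) {
    if (!lapse && g <= params$deadline_ms) {
      press <- g
      peak_ms <- onset + params$burst_rise_ms
      amp <- params$burst_amp
    }
  } else {
    sl <- params$stop_latency_ms + rnorm(1, 0, params$stop_latency_sd_ms)
    stop_finish <- ssd_ms + sl
    if (lapse || g > params$deadline_ms) {
      stop_wins <- TRUE
      phenotype <- "NO_EMG"
    } else if (g <= stop_finish) {
      stop_wins <- FALSE
      phenotype <- "FULL_PRESS"
      press <- g
      peak_ms <- onset + params$burst_rise_ms
      amp <- params$burst_amp
    } else {
      stop_wins <- TRUE
      # Two independent variance components of the peripheral cancellation:
      # whether the efferent cut caught the burst before activation onset
      # (t_cut), and where the truncated envelope actually peaks (t_peak).
      # Decoupling them keeps the realised peak latencies unbiased with
      # respect to the configured mean within the PARTIAL subset.
      t_cut <- ssd_ms + params$cancel_peak_latency_ms +
        rnorm(1, 0, params$cancel_jitter_sd_ms)
      if (onset < t_cut) {
        phenotype <- "PARTIAL"
        t_peak <- ssd_ms + params$cancel_peak_latency_ms +
          rnorm(1, 0, params$cancel_jitter_sd_ms)
        t_peak <- max(t_peak, onset + 5, ssd_ms + 1)
        cancel_peak <- t_peak - ssd_ms
        peak_ms <- t_peak
        frac <- min(1, (t_peak - onset) / params$burst_rise_ms)
        amp <- params$burst_amp * (0.3 + 0.6 * frac)
      } else {
        phenotype <- "NO_EMG"
      }
    }
  }

  responded <- !is.na(press)
  resp_hand <- NA_character_
  correct <- NA
  if (responded) {
    wrong <- runif(1) < params$choice_error_rate
    resp_hand <- if (wrong) setdiff(HANDS, hand) else hand
    correct <- !wrong
  }

  trace <- NULL
  if (emg) {
    ax <- emg_trace_axis(params)
    trace <- matrix(0, nrow = ax$n, ncol = 2,
                    dimnames = list(NULL, HANDS))
    for (side in HANDS) {
      env <- numeric(ax$n)
      burst_side <- if (responded) resp_hand else hand
      if (side == burst_side && amp > 0) {
        width <- if (identical(phenotype, "PARTIAL")) {
          # keep the truncation peak locally symmetric: the envelope must
          # rise from ~0 at onset, or smoothing biases the peak estimate
          min(params$partial_width_ms, (peak_ms - onset) / 2.5)
        } else {
          params$burst_fall_ms
        }
        env <- amp * burst_envelope(ax$t_ms, onset, peak_ms, width)
      }
      trace[, side] <- synth_trace(params, env)
    }
  }

  list(
    behaviour = tibble::tibble(
      rt_ms = press, responded = responded, resp_hand = resp_hand,
      correct_choice = correct, go_omission = !is_stop && !responded
    ),
    truth = tibble::tibble(
      true_go_rt_ms = if (lapse) NA_real_ else g,
      true_stop_wins = stop_wins,
      true_phenotype = phenotype,
      true_cancel_peak_ms = cancel_peak,
      true_onset_ms = if (amp > 0) onset else NA_real_,
      true_peak_ms = peak_ms,
      true_amp = amp
    ),
    trace = trace
  )
}

#' Simulate a full session with adaptive SSD staircasing
#'
#' Runs [simulate_trial()] over every row of a [generate_session()] design,
#' maintaining one SSD staircase per (hand x congruency) cell for stop
#' conditions (initialised at `init_ssd_ms`, 50 ms steps). Practice trials
#' are simulated and retain their flag.
#'
#' @param params a [race_params()].
#' @param design a `session_design`.
#' @param seed integer seed (local to this call).
#' @param emg synthesise per-trial EMG traces?
#' @param init_ssd_ms,step_ms,floor_ms staircase settings.
#' @param subject subject label stamped on every row.
#' @return A `sim_session` list: `trials` (behaviour table with realised
#'   `ssd_ms`), `truth`, `traces` (list of samples x 2 matrices or `NULL`),
#'   `staircases`, `params`, `fs`, `t0_s`.
#' @export
simulate_session <- function(params, design, seed = NULL, emg = TRUE,
                             init_ssd_ms = 200, step_ms = 50, floor_ms = 0,
                             subject = "S01") {
  stopifnot(inherits(params, "race_params"))
  with_seed(seed, {
    stair <- list()
    n <- nrow(design)
    beh <- vector("list", n)
    tru <- vector("list", n)
    traces <- if (emg) vector("list", n) else NULL
    for (i in seq_len(n)) {
      row <- design[i, ]
      ssd <- NA_real_
      key <- paste(row$hand, row$congruency, sep = ":")
      if (row$is_stop) {
        if (is.null(stair[[key]])) {
          stair[[key]] <- staircase_state(init_ssd_ms, step_ms, floor_ms, key)
        }
        ssd <- stair[[key]]$ssd_ms
      }
      out <- simulate_trial(params, row$condition, row$congruency, row$hand,
                            is_stop = row$is_stop, ssd_ms = ssd, emg = emg)
      if (row$is_stop) {
        stair[[key]] <- staircase_update(stair[[key]],
                                         !out$behaviour$responded)
      }
      beh[[i]] <- out$behaviour
      tru[[i]] <- out$truth
      if (emg) traces[[i]] <- out$trace
    }
    trials <- tibble::as_tibble(as.data.frame(design))
    trials$subject <- subject
    # realised SSDs: replay each staircase history in trial order
    ssds <- rep(NA_real_, n)
    hist <- lapply(stair, function(s) s$history)
    counters <- setNames(rep(0L, length(hist)), names(hist))
    for (i in which(design$is_stop)) {
      key <- paste(design$hand[i], design$congruency[i], sep = ":")
      counters[key] <- counters[key] + 1L
      ssds[i] <- hist[[key]]$ssd_ms[counters[key]]
    }
    trials$ssd_ms <- ssds
    trials <- dplyr::bind_cols(trials, dplyr::bind_rows(beh))
    structure(list(trials = trials, truth = dplyr::bind_rows(tru),
                   traces = traces, staircases = stair, params = params,
                   fs = params$fs_emg, t0_s = -params$trace_pre_s),
              class = "sim_session")
  })
}

#' Simulate a staircased stream of stop trials
#'
#' Stop-trial-only convenience generator for staircase-convergence and
#' Cancel-Time recovery studies: the one-up/one-down staircase only updates
#' on stop trials, so interleaved go trials are not needed to reproduce its
#' dynamics. One independent staircase per hand (and per congruency level if
#' several are given).
#'
#' @inheritParams simulate_session
#' @param n_per_cell number of stop trials per (hand x congruency) cell.
#' @param condition task context stamped on the trials.
#' @param congruency congruency levels to include.
#' @return A `sim_session` (all trials `is_stop = TRUE`, `practice = FALSE`).
#' @export
simulate_stop_trials <- function(params, n_per_cell, seed = NULL, emg = TRUE,
                                 condition = "SST", congruency = "NONE",
                                 init_ssd_ms = 200, step_ms = 50,
                                 floor_ms = 0, subject = "S01") {
  cells <- expand.grid(hand = HANDS, congruency = congruency,
                       stringsAsFactors = FALSE)
  design <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(k) {
    tibble::tibble(condition = condition,
                   congruency = cells$congruency[k],
                   hand = cells$hand[k], is_stop = TRUE)
  }))
  design <- design[rep(seq_len(nrow(design)), each = n_per_cell), ]
  # interleave cells so staircases progress together
  design <- design[order(rep(seq_len(n_per_cell), times = nrow(cells))), ]
  design$trial_index <- seq_len(nrow(design))
  design$fixation_s <- 0.85
  design$practice <- FALSE
  simulate_session(params, design, seed = seed, emg = emg,
                   init_ssd_ms = init_ssd_ms, step_ms = step_ms,
                   floor_ms = floor_ms, subject = subject)
}
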