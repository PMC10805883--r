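#' Draw fixation durations from a truncated exponential distribution
#'
#' Inter-trial fixation periods are jittered to prevent temporal anticipation
#' of the go cue: durations follow an exponential distribution truncated to a
#' fixed support (0.6--1.1 s by default). Sampling is by inversion of the
#' truncated CDF, so every draw lies inside `[lo, hi]`.
#'
#' @param n number of draws.
#' @param lo,hi truncation bounds in seconds; `0 < lo < hi` required.
#' @param rate exponential rate (per second) before truncation. Only the
#'   support is normative for the task; the rate shapes how strongly short
#'   fixations are favoured.
#' @return Numeric vector of `n` durations in seconds.
#' @examples
#' set.seed(1)
#' range(sample_fixation(1000))
#' @export
sample_fixation <- function(n = 1, lo = 0.6, hi = 1.1, rate = 2) {
  if (!is.finite(lo) || !is.finite(hi) || !is.finite(rate) ||
      lo <= 0 || hi <= lo || rate <= 0) {
    stopc_abort("`sample_fixation()` needs finite 0 < lo < hi and rate > 0",
                "stopcancel_invalid_parameter")
  }
  u <- runif(n)
  # inverse CDF of Exp(rate) conditioned on [lo, hi]
  p_span <- 1 - exp(-rate * (hi - lo))
  lo - log(1 - u * p_span) / rate
}

#' Mean of the truncated exponential fixation distribution
#'
#' Closed form used for calibration and testing:
#' `lo + 1/rate - (hi - lo) / (exp(rate * (hi - lo)) - 1)`.
#'
#' @inheritParams sample_fixation
#' @return Expected duration in seconds.
#' @export
fixation_mean <- function(lo = 0.6, hi = 1.1, rate = 2) {
  lo + 1 / rate - (hi - lo) / (expm1(rate * (hi - lo)))
}

default_trial_counts <- function() {
  list(
    CRT     = list(n_trials = 32L,  n_practice = 8L),
    FLANKER = list(n_trials = 180L, n_practice = 12L),
    SST     = list(n_trials = 120L, n_practice = 8L),
    SSFT    = list(n_trials = 360L, n_practice = 16L)
  )
}

condition_congruencies <- function(condition) {
  if (condition %in% c("CRT", "SST")) "NONE"
  else c("CONGRUENT", "INCONGRUENT", "NEUTRAL")
}

condition_has_stops <- function(condition) condition %in% c("SST", "SSFT")

STOP_FRACTION <- 0.3

#' Generate a session trial sequence
#'
#' Builds the full, seed-reproducible trial list for one task condition:
#' choice reaction time (CRT), flanker (FLANKER), stop-signal (SST) or the
#' combined stop-signal flanker task (SSFT). Left/right stimuli occur with
#' equal frequency, congruency levels (where present) occur with equal
#' frequency, and stop signals occur on 30% of SST/SSFT trials, balanced
#' across every (hand x congruency) cell. Practice trials are generated
#' first and flagged `practice = TRUE`; analyses downstream exclude them.
#'
#' @param condition one of `"CRT"`, `"FLANKER"`, `"SST"`, `"SSFT"`.
#' @param seed integer seed controlling trial order and fixation jitter.
#' @param n_trials,n_practice trial counts; defaults follow the standard
#'   session sizes (CRT 32, FLANKER 180, SST 120, SSFT 360 test trials).
#'   `n_trials` must divide evenly into the condition's design cells, and for
#'   stop conditions the 30% stop share must also split evenly across cells.
#' @param fixation_rate rate of the truncated-exponential fixation jitter.
#' @return A `session_design`: a tibble of trials (`trial_index`, `condition`,
#'   `congruency`, `hand`, `is_stop`, `fixation_s`, `practice`) with the seed
#'   and per-cell counts attached as attributes.
#' @examples
#' d <- generate_session("SSFT", seed = 1)
#' nrow(d)           # practice + test trials
#' sum(!d$practice)  # 360
#' @export
generate_session <- function(condition, seed,
                             n_trials = NULL, n_practice = NULL,
                             fixation_rate = 2) {
  condition <- match.arg(condition, CONDITIONS)
  defaults <- default_trial_counts()[[condition]]
  n_trials <- as.integer(n_trials %||% defaults$n_trials)
  n_practice <- as.integer(n_practice %||% defaults$n_practice)

  congr <- condition_congruencies(condition)
  cells <- expand.grid(hand = HANDS, congruency = congr,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  if (n_trials %% n_cells != 0) {
    stopc_abort(sprintf(
      "%s: n_trials = %d does not divide into %d (hand x congruency) cells",
      condition, n_trials, n_cells), "stopcancel_design_error")
  }
  per_cell <- n_trials %/% n_cells
  if (condition_has_stops(condition)) {
    n_stop_total <- STOP_FRACTION * n_trials
    if (abs(n_stop_total - round(n_stop_total)) > 1e-9 ||
        round(n_stop_total) %% n_cells != 0) {
      stopc_abort(sprintf(
        "%s: 30%% of %d trials does not split evenly across %d cells",
        condition, n_trials, n_cells), "stopcancel_design_error")
    }
    stop_per_cell <- as.integer(round(n_stop_total)) %/% n_cells
  } else {
    stop_per_cell <- 0L
  }

  build_cell <- function(hand, congruency) {
    tibble::tibble(
      condition = condition,
      congruency = congruency,
      hand = hand,
      is_stop = rep(c(TRUE, FALSE), c(stop_per_cell, per_cell - stop_per_cell))
    )
  }

  with_seed(seed, {
    test <- dplyr::bind_rows(Map(build_cell, cells$hand, cells$congruency))
    test <- test[sample.int(nrow(test)), , drop = FALSE]
    practice <- practice_block(condition, n_practice, congr)
    trials <- dplyr::bind_rows(practice, test)
    trials$practice <- rep(c(TRUE, FALSE), c(nrow(practice), nrow(test)))
    trials$fixation_s <- sample_fixation(nrow(trials), rate = fixation_rate)
    trials$trial_index <- seq_len(nrow(trials))
    trials <- trials[, c("trial_index", "condition", "congruency", "hand",
                         "is_stop", "fixation_s", "practice")]
    counts <- dplyr::count(trials[!trials$practice, ],
                           .data$hand, .data$congruency, .data$is_stop)
    structure(trials, class = c("session_design", class(trials)),
              seed = seed, counts_by_cell = counts)
  })
}

# Practice trials mimic the test composition as closely as the (small)
# counts allow; they are flagged and excluded from every analysis, so exact
# cell balance is not enforced here.
practice_block <- function(condition, n_practice, congr) {
  if (n_practice == 0L) {
    return(tibble::tibble(condition = character(), congruency = character(),
                          hand = character(), is_stop = logical()))
  }
  hands <- rep_len(HANDS, n_practice)
  cg <- rep_len(congr, n_practice)
  n_stop <- if (condition_has_stops(condition)) {
    as.integer(round(STOP_FRACTION * n_practice))
  } else 0L
  is_stop <- rep(FALSE, n_practice)
  if (n_stop > 0) {
    is_stop[seq(1L, n_practice, length.out = n_stop)] <- TRUE
  }
  out <- tibble::tibble(condition = condition, congruency = cg,
                        hand = hands, is_stop = is_stop)
  out[sample.int(n_practice), , drop = FALSE]
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %s: %d trials (%d practice), seed %s\n",
              x$condition[1], nrow(x), sum(x$practice),
              format(attr(x, "seed"))))
  NextMethod()
}

#' Create a stop-signal-delay staircase state
#'
#' One staircase tracks one (hand, congruency) cell. The SSD starts at
#' `ssd_ms` (200 ms by convention) and moves one `step_ms` (50 ms) per stop
#' trial: up after a successful stop, down after a failed stop, clamped at
#' `floor_ms`. This one-up/one-down rule drives long-run stop success
#' towards 50%.
#'
#' @param ssd_ms initial stop-signal delay in ms.
#' @param step_ms staircase step in ms.
#' @param floor_ms lowest admissible SSD (clamp, no underflow).
#' @param key optional label, e.g. `"LEFT:NONE"`.
#' @return A `staircase_state` list with an update `history`.
#' @export
staircase_state <- function(ssd_ms = 200, step_ms = 50, floor_ms = 0,
                            key = NA_character_) {
  stopifnot(ssd_ms >= floor_ms, step_ms > 0)
  structure(list(key = key, ssd_ms = ssd_ms, step_ms = step_ms,
                 floor_ms = floor_ms,
                 history = data.frame(ssd_ms = numeric(),
                                      stop_success = logical())),
            class = "staircase_state")
}

#' Advance a staircase after one stop trial
#'
#' @param state a [staircase_state()].
#' @param stop_success `TRUE` if the response was successfully withheld.
#' @return The updated state; `state$ssd_ms` holds the SSD for the *next*
#'   stop trial in this cell, and the realised (pre-update) SSD is appended
#'   to `state$history`.
#' @export
staircase_update <- function(state, stop_success) {
  stopifnot(inherits(state, "staircase_state"), is.logical(stop_success))
  state$history <- rbind(state$history,
                         data.frame(ssd_ms = state$ssd_ms,
                                    stop_success = stop_success))
  state$ssd_ms <- if (stop_success) {
    state$ssd_ms + state$step_ms
  } else {
    max(state$ssd_ms - state$step_ms, state$floor_ms)
  }
  state
}

#' Flag a go response as too slow for feedback purposes
#'
#' Participants receive "You've slowed down!" feedback when a go RT exceeds
#' their reference mean by more than 150 ms; the reference is the mean CRT
#' (or, in the combined task, the congruency-matched flanker-task mean).
#' Strict inequality: an RT exactly 150 ms above the reference is not
#' flagged.
#'
#' @param rt_ms observed go reaction time (ms).
#' @param ref_mean_rt_ms the participant's reference mean RT (ms).
#' @param margin_ms slowdown margin (ms).
#' @return Logical.
#' @export
slow_feedback_flag <- function(rt_ms, ref_mean_rt_ms, margin_ms = 150) {
  stopifnot(is.finite(rt_ms), is.finite(ref_mean_rt_ms))
  rt_ms > ref_mean_rt_ms + margin_ms
}

#' Write / read a session design as TSV
#'
#' One row per trial, header included; round-trips [generate_session()]
#' output (the seed attribute is stored in a comment-free extra column).
#'
#' @param design a `session_design`.
#' @param path file path.
#' @return `write_session_tsv()` returns `path` invisibly;
#'   `read_session_tsv()` returns a tibble of trials.
#' @export
write_session_tsv <- function(design, path) {
  df <- as.data.frame(design)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  if (!file.exists(path)) {
    stopc_abort(sprintf("trial TSV not found: %s", path),
                "stopcancel_missing_input")
  }
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
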