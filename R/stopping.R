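#' Integration-method stop-signal reaction time
#'
#' Classic integration estimator under the independent horse-race model: go
#' omissions are replaced with the subject's slowest go RT, the augmented go
#' RT distribution is sorted ascending, the RT at rank
#' `ceiling(p_respond * N)` (1-based) is taken as the point where the stop
#' process finishes, and the mean realised SSD is subtracted.
#'
#' @param go_rts_ms go-trial reaction times (ms), screened of choice errors.
#' @param n_go_omissions number of go omissions to replace with the slowest
#'   RT.
#' @param p_respond probability of responding on stop trials, strictly
#'   inside (0, 1).
#' @param mean_ssd_ms mean realised stop-signal delay (ms).
#' @return SSRT in ms.
#' @examples
#' compute_ssrt_integration(c(300, 350, 400, 450, 500), 0, 0.4, 200)  # 150
#' @export
compute_ssrt_integration <- function(go_rts_ms, n_go_omissions, p_respond,
                                     mean_ssd_ms) {
  if (length(go_rts_ms) == 0) {
    stopc_abort("no go RTs", "stopcancel_undefined_ssrt")
  }
  if (!is.finite(p_respond) || p_respond <= 0 || p_respond >= 1) {
    stopc_abort("SSRT undefined for p(respond|stop) of 0 or 1",
                "stopcancel_undefined_ssrt")
  }
  aug <- sort(c(go_rts_ms, rep(max(go_rts_ms), n_go_omissions)))
  rank <- ceiling(p_respond * length(aug))
  aug[rank] - mean_ssd_ms
}

#' Horse-race-model validity screening for a stopping cell
#'
#' SSRT is meaningful only where the independent race's signatures hold:
#' (i) the mean failed-stop RT is faster than the mean go RT, and (ii) the
#' staircase kept stop success within 25--75% (inclusive). Cells failing
#' either check are flagged and excluded from SSRT estimation. With no
#' failed stops the RT comparison is undefined and the cell is invalid.
#'
#' @param go_rts_ms screened go RTs (ms).
#' @param stop_responded logical per stop trial: did a press occur?
#' @param failed_stop_rts_ms RTs of failed stops (ms).
#' @return List: `race_rt_ok`, `success_in_band`, `valid`, `p_respond`,
#'   `reason` (`NA` when valid).
#' @export
race_validity <- function(go_rts_ms, stop_responded, failed_stop_rts_ms) {
  p_respond <- mean(stop_responded)
  success <- 1 - p_respond
  success_in_band <- success >= 0.25 && success <= 0.75
  race_rt_ok <- if (length(failed_stop_rts_ms) == 0) {
    NA
  } else {
    mean(failed_stop_rts_ms) < mean(go_rts_ms)
  }
  valid <- isTRUE(race_rt_ok) && success_in_band
  reason <- if (valid) NA_character_
  else if (!isTRUE(race_rt_ok) && is.na(race_rt_ok)) "no failed stops"
  else if (!isTRUE(race_rt_ok)) "mean failed-stop RT >= mean go RT"
  else "stop success outside 25-75%"
  list(race_rt_ok = race_rt_ok, success_in_band = success_in_band,
       valid = valid, p_respond = p_respond, reason = reason)
}

#' Proportion of stop trials with a partial EMG response
#'
#' @param premg logical (or 0/1) per stop trial.
#' @return Fraction in `[0, 1]`.
#' @export
prEMG_proportion <- function(premg) {
  if (length(premg) == 0) {
    stopc_abort("no stop trials", "stopcancel_processing_error")
  }
  mean(as.logical(premg))
}

#' Per-cell stopping summary (SSRT, Cancel Time, prEMG)
#'
#' Aggregates a processed trial table into one row per
#' subject x congruency cell, pooling left and right hands (mean SSD is
#' computed per hand first, then averaged, mirroring the per-hand
#' staircases). Go RTs feeding SSRT exclude practice trials, choice errors
#' and anticipatory responses (< 150 ms); go omissions are counted for the
#' slowest-RT replacement. Cells failing [race_validity()] carry `NA` SSRT
#' and are listed in the exclusion log.
#'
#' @param trials processed trial table ([emg_process_session()] output, or
#'   any table with the same behaviour columns; `premg`/`cancel_time_ms`
#'   may be absent if EMG was not processed).
#' @param anticipatory_ms anticipatory-RT screen applied to go RTs.
#' @return List: `stats` (tibble by subject x congruency: `n_go`,
#'   `n_go_omissions`, `n_stop`, `p_respond`, `mean_ssd_ms`, `ssrt_ms`,
#'   `race_rt_ok`, `success_in_band`, `valid`, `premg_proportion`,
#'   `mean_cancel_time_ms`, `cancel_times_ms` list-column) and `exclusions`
#'   (tibble: subject, congruency, reason).
#' @export
summarise_stopping <- function(trials, anticipatory_ms = 150) {
  stopifnot(all(c("subject", "congruency", "is_stop", "responded") %in%
                  names(trials)))
  trials <- trials[!trials$practice, ]
  has_premg <- "premg" %in% names(trials)

  cells <- unique(trials[trials$is_stop, c("subject", "congruency")])
  rows <- vector("list", nrow(cells))
  excl <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- cells$subject[i]; cg <- cells$congruency[i]
    cell <- trials[trials$subject == sub & trials$congruency == cg, ]
    go <- cell[!cell$is_stop, ]
    stop_tr <- cell[cell$is_stop, ]
    go_kept <- go[go$responded & go$correct_choice %in% TRUE &
                    go$rt_ms >= anticipatory_ms, ]
    n_omis <- sum(!go$responded)
    # mean SSD per hand, then averaged across hands
    mean_ssd <- mean(vapply(split(stop_tr$ssd_ms, stop_tr$hand), mean,
                            numeric(1)))
    v <- race_validity(go_kept$rt_ms, stop_tr$responded,
                       stop_tr$rt_ms[stop_tr$responded])
    ssrt <- NA_real_
    if (v$valid && v$p_respond > 0 && v$p_respond < 1 &&
        nrow(go_kept) > 0) {
      ssrt <- compute_ssrt_integration(go_kept$rt_ms, n_omis, v$p_respond,
                                       mean_ssd)
    }
    if (!v$valid) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        subject = sub, congruency = cg, reason = v$reason)
    }
    ct <- if (has_premg) stop_tr$cancel_time_ms[stop_tr$premg %in% TRUE]
          else numeric(0)
    rows[[i]] <- tibble::tibble(
      subject = sub, congruency = cg,
      n_go = nrow(go_kept), n_go_omissions = n_omis,
      n_stop = nrow(stop_tr),
      p_respond = v$p_respond, mean_ssd_ms = mean_ssd, ssrt_ms = ssrt,
      race_rt_ok = isTRUE(v$race_rt_ok),
      success_in_band = v$success_in_band, valid = v$valid,
      premg_proportion = if (has_premg) prEMG_proportion(stop_tr$premg)
                         else NA_real_,
      mean_cancel_time_ms = if (length(ct)) mean(ct) else NA_real_,
      cancel_times_ms = list(ct)
    )
  }
  list(stats = dplyr::bind_rows(rows),
       exclusions = if (length(excl)) dplyr::bind_rows(excl)
                    else tibble::tibble(subject = character(),
                                        congruency = character(),
                                        reason = character()))
}
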