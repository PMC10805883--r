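#' Screen go trials
#'
#' Removes practice trials, incorrect left/right choices, anticipatory
#' responses (RT < 150 ms, strict) and go omissions from the go-trial RT
#' pool, logging one reason per excluded trial. Screening is idempotent:
#' re-screening the kept set removes nothing.
#'
#' @param records trial table containing at least `is_stop`, `practice`,
#'   `responded`, `correct_choice`, `rt_ms`.
#' @param anticipatory_ms anticipatory threshold, ms (strict `<`).
#' @return List: `kept` (go trials passing every screen) and `excluded`
#'   (with a `reason` column). Together they partition the go trials.
#' @export
screen_go_trials <- function(records, anticipatory_ms = 150) {
  go <- records[!records$is_stop, ]
  reason <- rep(NA_character_, nrow(go))
  reason[go$practice] <- "practice"
  omit <- is.na(reason) & !go$responded
  reason[omit] <- "go omission"
  wrong <- is.na(reason) & !(go$correct_choice %in% TRUE)
  reason[wrong] <- "incorrect choice"
  antic <- is.na(reason) & go$rt_ms < anticipatory_ms
  reason[antic] <- sprintf("anticipatory (RT < %g ms)", anticipatory_ms)
  kept <- go[is.na(reason), ]
  excluded <- go[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = kept, excluded = excluded)
}

#' Flanker congruency reaction-time deltas
#'
#' Subject-level congruency effects per condition, from subject mean RTs:
#' `delta_incongruent_neutral_ms` (perceptual-inhibition cost) and
#' `delta_congruent_neutral_ms` (facilitation / congruency cost). Subjects
#' or conditions missing a congruency level yield `NA` deltas and are
#' listed in `incomplete`.
#'
#' @param kept screened go trials (see [screen_go_trials()]).
#' @return List: `metrics` (tibble: subject, condition, mean RT per
#'   congruency level, the two deltas) and `incomplete`.
#' @export
flanker_deltas <- function(kept) {
  fl <- kept[kept$congruency != "NONE", ]
  if (nrow(fl) == 0) {
    return(list(metrics = tibble::tibble(), incomplete = tibble::tibble()))
  }
  means <- fl |>
    dplyr::group_by(.data$subject, .data$condition, .data$congruency) |>
    dplyr::summarise(mean_rt = mean(.data$rt_ms), .groups = "drop") |>
    tidyr_pivot(names_from = "congruency", values_from = "mean_rt")
  for (lvl in c("CONGRUENT", "INCONGRUENT", "NEUTRAL")) {
    if (!lvl %in% names(means)) means[[lvl]] <- NA_real_
  }
  means$delta_incongruent_neutral_ms <- means$INCONGRUENT - means$NEUTRAL
  means$delta_congruent_neutral_ms <- means$CONGRUENT - means$NEUTRAL
  incomplete <- means[is.na(means$delta_incongruent_neutral_ms) |
                        is.na(means$delta_congruent_neutral_ms), ]
  list(metrics = means, incomplete = incomplete)
}

# minimal wide pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(df, names_from, values_from) {
  wide <- stats::reshape(as.data.frame(df), direction = "wide",
                         idvar = setdiff(names(df), c(names_from, values_from)),
                         timevar = names_from, v.names = values_from)
  names(wide) <- sub(paste0("^", values_from, "\\."), "", names(wide))
  tibble::as_tibble(wide)
}

#' Proactive slowing of go responses
#'
#' Mean go RT in a stop-expectation context minus the matched no-stop
#' baseline: SST against CRT, and SSFT against the congruency-matched
#' flanker-task trials. Positive values indicate strategic slowing (a
#' context-independence violation the feedback rule is meant to limit).
#'
#' @param kept screened go trials.
#' @return Tibble: subject, context condition, congruency, `slowing_ms`
#'   (`NA` with a note when the reference condition is missing).
#' @export
proactive_slowing <- function(kept) {
  out <- list()
  for (sub in unique(kept$subject)) {
    k <- kept[kept$subject == sub, ]
    # SST vs CRT
    if (any(k$condition == "SST")) {
      ref <- k$rt_ms[k$condition == "CRT"]
      sst <- k$rt_ms[k$condition == "SST"]
      out[[length(out) + 1]] <- tibble::tibble(
        subject = sub, condition = "SST", congruency = "NONE",
        slowing_ms = if (length(ref)) mean(sst) - mean(ref) else NA_real_)
    }
    # SSFT vs congruency-matched FLANKER
    if (any(k$condition == "SSFT")) {
      for (cg in unique(k$congruency[k$condition == "SSFT"])) {
        ref <- k$rt_ms[k$condition == "FLANKER" & k$congruency == cg]
        ssft <- k$rt_ms[k$condition == "SSFT" & k$congruency == cg]
        out[[length(out) + 1]] <- tibble::tibble(
          subject = sub, condition = "SSFT", congruency = cg,
          slowing_ms = if (length(ref)) mean(ssft) - mean(ref) else NA_real_)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(subject = character(), condition = character(),
                      congruency = character(), slowing_ms = numeric())
}
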