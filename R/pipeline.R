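#' Default pipeline configuration
#'
#' One JSON-serialisable document holding every tunable parameter of the
#' pipeline: task design counts, staircase settings, the synthetic-generator
#' parameters, EMG and fNIRS processing thresholds, and screening rules.
#' Printed-protocol values (staircase 200/50 ms, EMG 20--500 Hz order 4,
#' 3 SD burst threshold, 20 ms merge, 50 ms press rule, 10% prEMG amplitude
#' criterion, fNIRS prune/motion/low-pass settings, 4--7 s peak window)
#' are the defaults; everything else carries the package's documented
#' defaults.
#'
#' @param ... overrides as `name = value`; nested lists are merged by name.
#'   Unknown keys are rejected.
#' @param seed integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1L) {
  base <- list(
    seed = as.integer(seed),
    n_subjects = 2L,
    age_group = "young",
    conditions = c("CRT", "SST"),
    design = list(counts = default_trial_counts(), fixation_rate = 2),
    staircase = list(init_ssd_ms = 200, step_ms = 50, floor_ms = 0),
    race = unclass(race_params()),
    emg = list(bandpass_lo = 20, bandpass_hi = 500, bandpass_order = 4,
               envelope_lp = 10, burst_k = 3, merge_ms = 20,
               baseline_ms = 100, press_margin_ms = 50, premg_frac = 0.10),
    screening = list(anticipatory_ms = 150, slow_feedback_margin_ms = 150),
    fnirs = list(sim = unclass(haemo_sim_params()),
                 prune = list(d_range = c(1, 3), snr_thresh = 2,
                              sd_range_mm = c(0, 45)),
                 motion = list(t_motion = 0.5, t_mask = 1,
                               stdev_thresh = 9, amp_thresh = 100,
                               nSV = 0.97, max_iter = 5),
                 lowpass_hz = 0.5,
                 epoch = list(window_s = c(0, 10), baseline_s = c(0, 2),
                              peak_window_s = c(4, 7)))
  )
  overrides <- list(...)
  cfg <- merge_config(base, overrides, path = "config")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) {
    stopc_abort(sprintf("unknown %s key(s): %s", path,
                        paste(unknown, collapse = ", ")),
                "stopcancel_config_error")
  }
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]],
                                 paste(path, nm, sep = "$"))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `config_write()` returns `path` invisibly; `config_read()`
#'   returns the validated `pipeline_config` (unknown keys rejected).
#' @export
config_write <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  raw$n_subjects <- as.integer(raw$n_subjects)
  cfg <- pipeline_config(seed = raw$seed)
  raw$seed <- NULL
  cfg2 <- merge_config(unclass(cfg), raw, path = "config")
  structure(cfg2, class = "pipeline_config")
}

# Small stable content hash (polynomial rolling hash over the serialised
# JSON) stamped on every stage output so artefacts from different
# configurations are never mixed.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

race_params_from_config <- function(config) {
  p <- config$race
  fx <- p$flanker_effect_ms
  if (!is.null(names(fx))) fx <- unlist(fx)
  do.call(race_params, c(
    list(age_group = p$age_group %||% config$age_group),
    p[setdiff(names(p), c("age_group", "flanker_effect_ms"))],
    list(flanker_effect_ms = fx)))
}

#' Run the full simulate-and-analyse pipeline
#'
#' The package's canonical end-to-end smoke test: for each synthetic
#' subject, generates session designs, simulates behaviour and EMG with the
#' horse-race generator (staircased SSDs), processes the EMG (reference
#' from the subject's own CRT trials), summarises stopping (SSRT, Cancel
#' Time, prEMG) and go performance, simulates and processes an event-related
#' fNIRS recording for the stop condition, and writes every stage output
#' plus an aggregating `report.json` to `out_dir`. Deterministic given
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param fnirs also run the fNIRS branch?
#' @return Invisibly, the report list. Side effects: `trials.tsv`,
#'   `stop_stats.tsv`, `rt_metrics.tsv`, `exclusions.tsv`, `peaks.tsv`
#'   (if fNIRS), `config.json`, `report.json` in `out_dir`, all stamped
#'   with the config hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, fnirs = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  params <- race_params_from_config(config)

  all_trials <- list()
  stop_stats <- list()
  exclusions <- list()
  peaks <- list()

  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("S%02d", s)
    sub_seed <- config$seed + 1000L * s
    processed <- list()
    ref_peak <- NULL
    for (cond in config$conditions) {
      counts <- config$design$counts[[cond]]
      design <- generate_session(cond, seed = sub_seed + match(cond, CONDITIONS),
                                 n_trials = counts$n_trials,
                                 n_practice = counts$n_practice,
                                 fixation_rate = config$design$fixation_rate)
      needs_emg <- cond %in% c("CRT", "SST", "SSFT")
      sim <- simulate_session(params, design,
                              seed = sub_seed + 10L * match(cond, CONDITIONS),
                              emg = needs_emg,
                              init_ssd_ms = config$staircase$init_ssd_ms,
                              step_ms = config$staircase$step_ms,
                              floor_ms = config$staircase$floor_ms,
                              subject = subject)
      if (needs_emg) {
        proc <- emg_process_session(sim, ref_peak = ref_peak,
                                    amp_frac = config$emg$premg_frac)
        if (cond == "CRT") ref_peak <- proc$ref_peak
        processed[[cond]] <- proc$trials
      } else {
        processed[[cond]] <- sim$trials
      }
    }
    trials <- dplyr::bind_rows(processed)
    all_trials[[subject]] <- trials

    stop_conditions <- intersect(config$conditions, c("SST", "SSFT"))
    if (length(stop_conditions)) {
      stopping <- summarise_stopping(
        trials[trials$condition %in% stop_conditions, ],
        anticipatory_ms = config$screening$anticipatory_ms)
      stop_stats[[subject]] <- stopping$stats
      exclusions[[subject]] <- stopping$exclusions

      if (fnirs) {
        stop_trials <- trials[trials$condition %in% stop_conditions &
                                !trials$practice & trials$is_stop, ]
        iti <- 14
        events <- tibble::tibble(
          time_s = 20 + iti * (seq_len(nrow(stop_trials)) - 1),
          condition = ifelse(stop_trials$responded, "STOP_FAIL",
                             "STOP_SUCCESS"),
          outcome = ifelse(stop_trials$responded, "fail", "success"))
        sim_args <- config$fnirs$sim[
          names(config$fnirs$sim) %in% names(formals(haemo_sim_params))]
        hp <- do.call(haemo_sim_params, sim_args)
        duration <- max(events$time_s) + 30
        fn <- simulate_fnirs(hp, events, duration_s = duration,
                             seed = sub_seed + 77L)
        pr <- prune_channels(fn$series,
                             d_range = config$fnirs$prune$d_range,
                             snr_thresh = config$fnirs$prune$snr_thresh,
                             sd_range_mm = config$fnirs$prune$sd_range_mm)
        od <- to_optical_density(pr$series)
        mo <- config$fnirs$motion
        mc <- pca_motion_correct(od, nSV = mo$nSV, max_iter = mo$max_iter,
                                 t_motion = mo$t_motion, t_mask = mo$t_mask,
                                 stdev_thresh = mo$stdev_thresh,
                                 amp_thresh = mo$amp_thresh)
        lp <- lowpass_haemo(mc$od, cutoff_hz = config$fnirs$lowpass_hz)
        conc <- od_to_concentration(lp)
        hemi <- hemisphere_average(conc)
        ep <- epoch_and_average(hemi,
                                window_s = config$fnirs$epoch$window_s,
                                baseline_s = config$fnirs$epoch$baseline_s)
        for (k in seq_len(nrow(ep$epochs))) {
          pk <- peak_hbo2(ep$epochs$epoch[[k]],
                          window_s = config$fnirs$epoch$peak_window_s)
          peaks[[length(peaks) + 1]] <- tibble::tibble(
            subject = subject, hemisphere = ep$epochs$label[k],
            condition = ep$epochs$condition[k],
            outcome = ep$epochs$outcome[k], n = ep$epochs$n[k],
            peak_hbo2 = pk$peak_umol, peak_time_s = pk$peak_time_s)
        }
      }
    }
  }

  trials <- dplyr::bind_rows(all_trials)
  screened <- screen_go_trials(trials,
                               anticipatory_ms = config$screening$anticipatory_ms)
  deltas <- flanker_deltas(screened$kept)
  slowing <- proactive_slowing(screened$kept)
  stats <- dplyr::bind_rows(stop_stats)
  excl <- dplyr::bind_rows(exclusions)
  peaks_tbl <- if (length(peaks)) dplyr::bind_rows(peaks) else NULL

  write_stamped <- function(df, file) {
    path <- file.path(out_dir, file)
    df2 <- as.data.frame(df)
    df2$config_hash <- hash
    list_cols <- vapply(df2, is.list, logical(1))
    write.table(df2[, !list_cols, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    path
  }
  write_stamped(trials, "trials.tsv")
  if (nrow(stats)) write_stamped(stats, "stop_stats.tsv")
  write_stamped(screened$excluded, "exclusions.tsv")
  if (!is.null(excl) && nrow(excl)) write_stamped(excl, "stop_exclusions.tsv")
  if (nrow(deltas$metrics)) write_stamped(deltas$metrics, "rt_metrics.tsv")
  if (!is.null(peaks_tbl)) write_stamped(peaks_tbl, "peaks.tsv")
  config_write(config, file.path(out_dir, "config.json"))

  report <- list(
    config_hash = hash,
    n_subjects = config$n_subjects,
    conditions = config$conditions,
    go_trials_kept = nrow(screened$kept),
    go_trials_excluded = nrow(screened$excluded),
    stop_stats = if (nrow(stats)) {
      as.list(stats[, setdiff(names(stats), "cancel_times_ms")])
    } else NULL,
    stop_exclusions = if (!is.null(excl)) nrow(excl) else 0L,
    proactive_slowing_ms = if (nrow(slowing)) mean(slowing$slowing_ms,
                                                   na.rm = TRUE) else NA,
    fnirs_peaks = if (!is.null(peaks_tbl)) as.list(peaks_tbl) else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Verify that stage outputs share one configuration
#'
#' @param paths TSV files written by [run_pipeline()].
#' @return `TRUE` invisibly; error if hashes differ.
#' @export
check_config_hashes <- function(paths) {
  hashes <- vapply(paths, function(p) {
    if (!file.exists(p)) {
      stopc_abort(sprintf("missing stage output: %s", p),
                  "stopcancel_missing_input")
    }
    unique(read.delim(p)$config_hash)[1]
  }, character(1))
  if (length(unique(hashes)) > 1) {
    stopc_abort("stage outputs come from different configurations",
                "stopcancel_config_error")
  }
  invisible(TRUE)
}
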