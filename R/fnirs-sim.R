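#' fNIRS forward-simulation parameters
#'
#' Parameters of the synthetic continuous-wave fNIRS generator: event-related
#' haemodynamic responses (double-gamma HRF scaled per condition, in umol of
#' HbO2, with proportional HbR decrease), sinusoidal physiological nuisance
#' (cardiac ~1 Hz, respiration ~0.3 Hz, Mayer waves ~0.1 Hz), white sensor
#' noise and occasional motion spikes, all mixed in optical-density units
#' through the same extinction-coefficient table the analysis inverts.
#'
#' @param amplitude_by_condition named numeric, peak HbO2 excursion (umol)
#'   per event condition label.
#' @param hbr_ratio HbR excursion as a (negative) fraction of HbO2.
#' @param cardiac_hz,resp_hz,mayer_hz physiological nuisance frequencies.
#' @param cardiac_amp,resp_amp,mayer_amp their amplitudes, OD units.
#' @param white_sd white noise sd, OD units.
#' @param motion_spike_rate expected motion spikes per minute.
#' @param spike_amp,spike_dur_s spike amplitude (OD units) and duration.
#' @param fs_fnirs sampling rate, Hz (7.8125 by instrument convention).
#' @param baseline_intensity mean detector intensity, recorded units.
#' @param separation_mm source-detector separation of the montage.
#' @param dpf named differential pathlength factors per wavelength.
#' @param n_per_hemisphere,n_midline montage size (10 + 10 + midline).
#' @return A `haemo_sim_params` list.
#' @export
haemo_sim_params <- function(amplitude_by_condition = c(GO = 0.2,
                                                        STOP_SUCCESS = 0.4,
                                                        STOP_FAIL = 0.25),
                             hbr_ratio = -1 / 3,
                             cardiac_hz = 1.0, resp_hz = 0.3, mayer_hz = 0.1,
                             cardiac_amp = 0.01, resp_amp = 0.008,
                             mayer_amp = 0.005, white_sd = 0.003,
                             motion_spike_rate = 0.5, spike_amp = 0.3,
                             spike_dur_s = 0.4,
                             fs_fnirs = 7.8125, baseline_intensity = 2,
                             separation_mm = 30, dpf = default_dpf(),
                             n_per_hemisphere = 10, n_midline = 2) {
  stopifnot(fs_fnirs > 0, baseline_intensity > 0, separation_mm > 0)
  amplitude_by_condition <- unlist(amplitude_by_condition)
  dpf <- unlist(dpf)
  structure(as.list(environment()), class = "haemo_sim_params")
}

#' Build the prefrontal channel montage
#'
#' @param params a [haemo_sim_params()].
#' @return Tibble: `channel`, `source`, `detector`, `hemisphere`
#'   (LEFT/RIGHT/MIDLINE), `separation_mm`.
#' @export
make_montage <- function(params = haemo_sim_params()) {
  hemis <- c(rep("LEFT", params$n_per_hemisphere),
             rep("RIGHT", params$n_per_hemisphere),
             rep("MIDLINE", params$n_midline))
  n <- length(hemis)
  tibble::tibble(
    channel = seq_len(n),
    source = 1L + (seq_len(n) - 1L) %/% 2L,
    detector = 1L + (seq_len(n) - 1L) %/% 3L,
    hemisphere = hemis,
    separation_mm = params$separation_mm
  )
}

new_haemo_series <- function(data, channels, wavelengths, fs, events,
                             domain, species = NULL) {
  structure(list(data = data, channels = channels,
                 wavelengths = wavelengths, fs = fs, events = events,
                 domain = domain, species = species),
            class = "haemo_series")
}

#' @export
print.haemo_series <- function(x, ...) {
  cat(sprintf("<haemo_series> %s: %d channels x %d x %d samples @ %.4f Hz\n",
              x$domain, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

haemo_time_axis <- function(series) {
  (seq_len(dim(series$data)[3]) - 1) / series$fs
}

# Forward modified Beer-Lambert model: concentrations (umol) -> delta-OD.
conc_to_od_forward <- function(hbo2, hbr, separation_mm, dpf) {
  eps <- extinction_coefficients()
  d_cm <- separation_mm / 10
  lapply(rownames(eps), function(wl) {
    (eps[wl, "HbO2"] * hbo2 + eps[wl, "HbR"] * hbr) * 1e-6 *
      d_cm * dpf[[wl]]
  }) |> setNames(rownames(eps))
}

#' Simulate a continuous fNIRS intensity recording
#'
#' Generates raw detector intensities for the full montage: per-channel
#' optical density is assembled from HRF-convolved event responses pushed
#' through the forward modified Beer-Lambert model, plus sinusoidal
#' physiological nuisance (random phases per channel), white noise, and
#' Poisson-placed motion spikes shared across channels (a rank-one artifact
#' with random channel loadings). Intensity is `baseline * exp(-OD)`.
#'
#' @param params a [haemo_sim_params()].
#' @param events tibble/data.frame with `time_s`, `condition` and optionally
#'   `outcome`; conditions index `amplitude_by_condition`.
#' @param duration_s recording length, seconds.
#' @param seed integer seed (local).
#' @param physio,noise,spikes logical switches for each nuisance component;
#'   disable all three for an exact noiseless forward model.
#' @return A list: `series` (INTENSITY-domain `haemo_series`) and `truth`
#'   (`hbo2` channel x time matrix in umol, `hbr`, `spike_times_s`,
#'   `amplitudes`).
#' @export
simulate_fnirs <- function(params, events, duration_s, seed = NULL,
                           physio = TRUE, noise = TRUE, spikes = TRUE) {
  stopifnot(inherits(params, "haemo_sim_params"))
  events <- tibble::as_tibble(events)
  if (!all(events$time_s >= 0 & events$time_s <= duration_s)) {
    stopc_abort("events must fall within the recording duration",
                "stopcancel_invalid_parameter")
  }
  with_seed(seed, {
    montage <- make_montage(params)
    n_ch <- nrow(montage)
    t_s <- seq(0, duration_s, by = 1 / params$fs_fnirs)
    n_t <- length(t_s)

    hbo2_common <- numeric(n_t)
    for (i in seq_len(nrow(events))) {
      amp <- unname(params$amplitude_by_condition[[events$condition[i]]] %||% 0)
      if (amp != 0) {
        hbo2_common <- hbo2_common +
          amp * hrf_double_gamma(t_s - events$time_s[i])
      }
    }
    # mild channel-to-channel gain variation keeps hemispheric averaging
    # honest without breaking noiseless roundtrips at any single channel
    gains <- rep(1, n_ch)
    hbo2 <- outer(gains, hbo2_common)
    hbr <- params$hbr_ratio * hbo2

    spike_times <- numeric(0)
    spike_od <- matrix(0, n_ch, n_t)
    if (spikes && params$motion_spike_rate > 0) {
      n_spk <- stats::rpois(1, params$motion_spike_rate * duration_s / 60)
      if (n_spk > 0) {
        spike_times <- sort(runif(n_spk, 0, duration_s - params$spike_dur_s))
        for (ts in spike_times) {
          idx <- which(t_s >= ts & t_s < ts + params$spike_dur_s)
          loading <- runif(n_ch, 0.5, 1.5)
          spike_od[, idx] <- spike_od[, idx] +
            params$spike_amp * outer(loading, rep(1, length(idx)))
        }
      }
    }

    data <- array(NA_real_, dim = c(n_ch, 2, n_t),
                  dimnames = list(NULL, c("760", "850"), NULL))
    for (ch in seq_len(n_ch)) {
      od_hb <- conc_to_od_forward(hbo2[ch, ], hbr[ch, ],
                                  montage$separation_mm[ch], params$dpf)
      for (wl in c("760", "850")) {
        od <- od_hb[[wl]]
        if (physio) {
          od <- od +
            params$cardiac_amp * sin(2 * pi * params$cardiac_hz * t_s +
                                       runif(1, 0, 2 * pi)) +
            params$resp_amp * sin(2 * pi * params$resp_hz * t_s +
                                    runif(1, 0, 2 * pi)) +
            params$mayer_amp * sin(2 * pi * params$mayer_hz * t_s +
                                     runif(1, 0, 2 * pi))
        }
        if (noise) od <- od + rnorm(n_t, 0, params$white_sd)
        od <- od + spike_od[ch, ]
        data[ch, wl, ] <- params$baseline_intensity * exp(-od)
      }
    }
    series <- new_haemo_series(data, montage, c(760, 850), params$fs_fnirs,
                               events, "INTENSITY")
    list(series = series,
         truth = list(hbo2 = hbo2, hbr = hbr, spike_times_s = spike_times,
                      amplitudes = params$amplitude_by_condition))
  })
}
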