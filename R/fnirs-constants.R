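# Optical constants shared by the fNIRS forward simulator and the modified
# Beer-Lambert inversion. Sharing one table makes noiseless roundtrips exact.

#' Molar extinction coefficients for haemoglobin
#'
#' Compiled molar extinction coefficients (1/(cm*M)) for oxygenated and
#' deoxygenated haemoglobin at the two instrument wavelengths (760 and
#' 850 nm), from the standard compiled absorption spectra used across the
#' near-infrared spectroscopy literature.
#'
#' @param wavelengths numeric; must be a subset of 760/850 nm.
#' @return Matrix with one row per wavelength and columns `HbO2`, `HbR`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- matrix(c(1486.5865, 3843.707,
                  2526.391,  1798.643),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("760", "850"), c("HbO2", "HbR")))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab))) {
    stopc_abort("extinction table holds 760 and 850 nm only",
                "stopcancel_config_error")
  }
  tab[key, , drop = FALSE]
}

#' Default differential pathlength factors
#'
#' Wavelength-dependent scaling of the photon path through tissue used in
#' the modified Beer-Lambert law; adult-forehead values.
#'
#' @return Named numeric vector over wavelengths.
#' @export
default_dpf <- function() c(`760` = 6.0, `850` = 5.2)

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (peak ~5 s, undershoot ~15 s),
#' normalised so the positive peak equals 1: an event of amplitude `a` umol
#' contributes a concentration excursion peaking at `a`.
#'
#' @param t_s time since event onset, seconds (values < 0 give 0).
#' @param peak_s,under_s shape parameters of the response and undershoot
#'   gammas (their means, in seconds, at unit rate).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return Numeric vector, unit peak.
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, under_s = 16,
                             undershoot_ratio = 1 / 6) {
  raw <- function(t) {
    h <- numeric(length(t))
    pos <- t > 0
    tp <- t[pos]
    h[pos] <- stats::dgamma(tp, shape = peak_s, rate = 1) -
      undershoot_ratio * stats::dgamma(tp, shape = under_s, rate = 1)
    h
  }
  peak_val <- max(raw(seq(0, 30, by = 0.01)))
  raw(t_s) / peak_val
}
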