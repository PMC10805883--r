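Package: stopcancel
Title: Stop-Signal and Flanker Psychophysiology: Cancel Time, SSRT and
    Event-Related fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for response-inhibition psychophysiology built around the
    stop-signal paradigm: adaptive stop-signal-delay staircasing and trial
    design for choice-reaction, flanker, stop-signal and combined
    stop-signal-flanker tasks; surface-EMG burst detection with
    partial-response (prEMG) classification and trial-level Cancel Time
    estimation; integration-method stop-signal reaction time (SSRT) with
    horse-race-model validity screening; flanker congruency reaction-time
    metrics; and a simplified event-related functional near-infrared
    spectroscopy (fNIRS) chain (channel pruning, optical density, PCA motion
    correction, modified Beer-Lambert inversion, stimulus-locked epoch
    averaging and peak oxyhaemoglobin extraction). A horse-race-model
    synthetic-data generator produces behaviour, per-trial EMG traces and
    continuous fNIRS series with embedded ground truth for end-to-end
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
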