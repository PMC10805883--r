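---
title: "Models and methods in stopcancel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stopcancel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopcancel)
```

# Scope

`stopcancel` implements a complete stop-signal / flanker psychophysiology
analysis chain — task design with adaptive SSD staircasing, EMG-based
partial-response (prEMG) detection and Cancel Time estimation,
integration-method SSRT with race-model screening, flanker reaction-time
metrics, and an event-related prefrontal fNIRS chain — together with a
horse-race-model synthetic-data generator that exercises all of it with
embedded ground truth. This vignette is the package's own account of the
models, the tunable parameters, the numerical choices, and the limits of
what synthetic-data validation can show.

# Task design and the SSD staircase

Four conditions are supported. The choice-reaction task (CRT, 32 test
trials) and flanker task (180 trials; congruent, incongruent and neutral
flankers in equal numbers) establish baseline responding. The stop-signal
task (SST, 120 trials) and the combined stop-signal flanker task (SSFT,
360 trials) add a stop cue on 30% of trials, balanced over every
hand-by-congruency cell. Practice trials are generated first, flagged, and
excluded from every analysis. Fixation intervals are drawn from an
exponential distribution truncated to 0.6–1.1 s by inverse-CDF sampling;
the rate before truncation is not normative and defaults to 2 s⁻¹ — only
the support matters for preventing temporal anticipation, and
`fixation_mean()` gives the closed-form mean used by the calibration test.

Each (hand × congruency) cell owns an independent one-up/one-down
staircase: the SSD starts at 200 ms and moves 50 ms up after a successful
stop, 50 ms down after a failed one. For any monotone mapping from SSD to
response probability this rule has a stationary response rate of 50%,
which the test suite asserts both for an abstract psychometric function and
for the package's own generator. Design gaps resolved here: the SSD floor
is 0 ms (clamp, no underflow) with no explicit ceiling (the response
deadline, 1500 ms by default, bounds it in practice); the SSFT staircases
initialise at 200 ms per congruency cell rather than inheriting the SST
state; block structure is honoured for rest breaks only, so staircase
state persists across blocks; and trial order is a plain seeded
permutation with no run-length constraints.

# The synthetic generator

## Behaviour

Go RTs are ex-Gaussian — Normal(μ, σ) plus Exponential(τ) — the standard
descriptive model for RT distributions. Young-adult defaults are μ = 300,
σ = 40, τ = 80 ms; the older preset (μ = 360, σ = 50, τ = 110 ms) slows
and broadens the distribution. Congruency adds fixed shifts
(`flanker_effect_ms`, default +57 ms for incongruent flankers relative to
neutral); stop-expectation contexts add `proactive_slow_ms` (default 0,
i.e. context independence holds by construction). Attentional lapses
(`go_omission_rate`, 1%) produce go omissions with no muscle activity, and
`choice_error_rate` (2%) responds with the wrong hand.

On stop trials an independent stop process of duration
`stop_latency_ms` + Normal(0, `stop_latency_sd_ms`) races the go process.
If the go RT beats the stop finish, the trial is a failed stop with a
press (`FULL_PRESS`). Otherwise the stop wins, and the trial is classified
by whether muscle activation had already begun when the peripheral
cancellation arrived: EMG onset (go RT minus the electromechanical lead
`emg_onset_to_press_ms`) before the cancellation event gives a `PARTIAL`
trial whose envelope peaks `cancel_peak_latency_ms` after the stop signal;
onset after it gives `NO_EMG`, a noise-only trace. Using the cancellation
event — not the stop-process completion — as the `PARTIAL`/`NO_EMG`
boundary guarantees that a partial burst always rises before its
truncation peak, which the literal race ordering cannot (the cancellation
reaches the muscle earlier than the full stop latency).

Two bookkeeping subtleties keep the embedded truth unbiased. First, the
cancellation latency carries two *independent* jitter draws: one decides
whether the cut preceded activation onset, the other places the realised
envelope peak. Conditioning both decisions on a single draw would
selection-bias the realised peak latencies upward by several ms. Second,
the peak is clamped to fall after burst onset (and after the stop signal),
which together with the detectability of very brief bursts leaves a small
residual upward shift (~2–4 ms) in the recovered mean — well inside the
±10 ms recovery tolerance the tests enforce.

## Parameter choices that interact

`stop_latency_ms` (young default 190 ms), `cancel_peak_latency_ms`
(155 ms, the young-adult stop-task mean Cancel Time) and
`emg_onset_to_press_ms` (130 ms) jointly fix the geometry of partial
responses: the window of go RTs yielding a partial burst has width
`cancel + lead − stop_latency`. The defaults were chosen once so that
(i) partial bursts appear on roughly a quarter to a third of stop trials,
matching reported prEMG prevalence; (ii) rise-to-peak durations are long
enough for the bursts to survive the pipeline's own 10% amplitude
criterion; and (iii) the integration SSRT stays strictly above the mean
Cancel Time. A single-latency independent race cannot simultaneously
reproduce a ~100 ms SSRT-minus-Cancel-Time gap *and* realistic prEMG
prevalence; the package prioritises prevalence and recovery and asserts
the gap only as a strict ordering. The electromechanical lead of 130 ms
reflects typical first-dorsal-interosseous EMG-onset-to-press lags; the
50 ms figure used by the *analysis* is a minimum for causal linking, not a
mean, and conflating the two collapses the partial-response window.

## EMG traces

Traces span −0.2 to +1.6 s around the go signal at 2000 Hz, as
`noise_sd`·N(0,1) plus the burst envelope modulating an independent white
carrier — so the rectified signal has expectation proportional to the
envelope. Response bursts are Gaussian bumps (sd `burst_fall_ms` = 45 ms)
peaking `burst_rise_ms` = 120 ms after onset, gated sharply at onset
(3 ms time constant). Partial bursts are Gaussian about the truncation
peak with width `min(partial_width_ms, (peak − onset)/2.5)`: the adaptive
width keeps the peak locally symmetric even when onset falls close to it,
because an envelope truncated at the left and smoothed at 10 Hz would
otherwise report its peak ~9 ms late. Partial amplitude is
`burst_amp · (0.3 + 0.6·rise_fraction)`, in line with observed prEMG peaks
of roughly 30–50% of the CRT reference. Burst shapes are stipulations
designed for controllable recovery, not estimates of real envelope shape.

## fNIRS forward model

Per channel and wavelength (760/850 nm), optical density is assembled as
the modified Beer–Lambert forward image of the haemoglobin excursions —
HbO₂(t) is the double-gamma HRF (unit peak, maximum near 5 s) scaled by a
per-condition amplitude in µmol, HbR a fixed negative fraction (−1/3) —
plus sinusoidal nuisance at cardiac (1.0 Hz), respiratory (0.3 Hz) and
Mayer-wave (0.1 Hz) frequencies with random phases, white noise, and
Poisson-placed motion spikes sharing one loading vector across channels
(a rank-one artifact). Intensity is `baseline · exp(−OD)`. The forward
model and the analysis inversion share one extinction-coefficient table
and DPF set (6.0 / 5.2; compiled standard values), so noiseless
round-trips are exact by construction — a deliberate property the
acceptance suite exploits.

# EMG analysis

The chain is: fourth-order Butterworth band-pass 20–500 Hz, full-wave
rectification, fourth-order low-pass at 10 Hz, negative ripple clipped.
All filtering is zero-phase (forward–backward), so burst timing is not
shifted by group delay; the trade-off is non-causal smoothing, discussed
below. The hardware's analogue 20–1000 Hz acquisition filter is treated
as a property of the recording, emulated implicitly by the generator's
band-limited carrier, and not re-applied.

Burst detection thresholds the envelope at baseline mean + 3 SD, where the
baseline is the quietest 100 ms window of the trial (the window with the
minimal mean; its own SD supplies the spread). Supra-threshold runs closer
than 20 ms merge; peaks are the within-burst argmax with ties broken by
the earliest sample; crossings are resolved at the sample level with no
sub-sample interpolation. A brute-force per-sample scan reproduces the
detector exactly on randomised envelopes, which is asserted in the tests.

The response-generating burst on a pressed trial is the *last* burst whose
onset is after the go signal and at least 50 ms before the press. A
successful stop trial is a prEMG event when its latest qualifying burst
(i) starts after the go signal, (ii) peaks after the SSD — implemented
literally as `peak > ssd`, with no extra margin — and (iii) peaks above
10% of the participant's mean CRT response-burst peak. The 10% reference
uses CRT trials (consistent with the normalisation convention; the
reference source is configurable). Cancel Time is peak minus SSD and is
strictly positive by construction of criterion (ii).

**Timing accuracy.** The 10 Hz envelope smooths over tens of
milliseconds, so a floor-level threshold crossing lags true burst onset
systematically (about +20 ms at the generator's default SNR, with a few
ms of trial-to-trial spread); no burst shape avoids both this lag and the
opposite early-crossing bias of a step-like rise. Onset timing only
gates the 50 ms causal-link rule, where a 20 ms error is immaterial.
Peak timing, which Cancel Time actually uses, is recovered with ~0.2 ms
bias because the generator's peaks are locally symmetric under the
smoothing kernel. The tests assert exactly these properties rather than
an onset accuracy the filter physics cannot deliver.

# Stopping statistics

The integration SSRT replaces go omissions with the subject's slowest go
RT, sorts the augmented distribution, takes the RT at 1-based rank
`⌈p(respond|stop) · N⌉` (ties inherit sorted order), and subtracts the
mean realised SSD — computed per hand first, then averaged, mirroring the
per-hand staircases. SSRT is undefined at response rates of 0 or 1 and the
cell is then flagged rather than extrapolated. Race-model screening
excludes cells where mean failed-stop RT is not faster than mean go RT or
stop success leaves the inclusive 25–75% band; with no failed stops the RT
comparison is undefined and the cell is invalid. Go RTs feeding SSRT are
pre-screened of choice errors and anticipations (< 150 ms, strict), and
hands are pooled within subject × congruency.

# fNIRS analysis

Channels are pruned on mean raw intensity (dRange `[1, 3]`, interpreted
literally in recorded units and configurable because unit conventions
vary), intensity SNR ≥ 2 at both wavelengths, and source–detector
separation within `[0, 45]` mm. Optical density is `−ln(I/mean I)`, making
the chain invariant to uniform intensity rescaling; its arbitrary
per-channel offset is removed later by epoch baseline-zeroing. Motion is
flagged where the OD excursion within any 0.5 s window exceeds 9 deriv-SDs
or 100 OD units on any channel, dilated 1 s each side. PCA correction
operates on the flagged samples only: an *uncentered* SVD of the
(time × channel·wavelength) segment matrix, removing the smallest leading
component set reaching 97% cumulative variance, with up to 5
detect–correct iterations and linear-ramp stitching so corrected runs
rejoin their clean neighbours continuously. Uncentered removal is a pure
projection, so flagged-but-clean samples are nearly untouched, and samples
outside the mask are provably never altered; column centering would leak
spike-contaminated means into clean rows. If a flagged segment has fewer
samples than channels the PCA is skipped with a warning. The 0.5 Hz
third-order zero-phase low-pass then attenuates cardiac power by more
than 98% while passing 0.05 Hz with < 1% loss.

Concentrations follow from the two-wavelength modified Beer–Lambert
inversion, `c = 10⁶ · E⁻¹ (ΔOD / (d·DPF))` in µmol with HbT = HbO₂ + HbR
appended; a singular extinction matrix is a configuration error.
Surviving non-midline channels are averaged per hemisphere (a hemisphere
with no survivors is reported missing, not silently imputed). Epochs span
0–10 s after each event, are zeroed on their 0–2 s baseline mean, averaged
by (condition, outcome) with pointwise 95% t-intervals, and events whose
window overruns the recording are dropped with a record. The activation
metric is the signed maximum of HbO₂ within 4–7 s (inclusive); the signed
maximum — not the absolute excursion — is used because the metric is a
*peak change*. Negative HbO₂/HbR correlation is a quality signal, not an
enforced constraint.

Machine-precision amplitude recovery in the noiseless round-trip requires
events aligned to the 7.8125 Hz sample grid and epochs free of a previous
event's HRF tail; misaligned events leave a ~10⁻⁴ discrepancy that is
sampling, not physics.

# What the tests do and do not show

Problem sizes in the suite — ≥ 2000 staircased stop trials for
convergence, ≥ 500 partial trials for Cancel-Time recovery (±10 ms),
1000-trial sessions for ≥ 95% phenotype agreement, 1000 random instances
for the SSRT oracle, 500 envelopes for the burst oracle — were chosen as
the smallest sets that make the Monte-Carlo error a small fraction of each
tolerance. Passing them shows the implementation is internally correct
and that parameters the generator embeds are recovered through the full
chain. It does not show that real EMG — with movement artifact,
non-stationary baselines, crosstalk and electrode drift — or real fNIRS
— with serially correlated physiology, scalp coupling and task-correlated
motion — will behave comparably; the generator's noise is stationary and
white by design. Trigger failures, violations of race independence,
short-separation regression and GLM-based HRF estimation are out of
scope, as are fitting race-model parameters to real data and any group
inference (mixed models are deliberately left to the established
packages).
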