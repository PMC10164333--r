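---
title: "Simulating and decoding a hybrid EEG/EOG interface for shared robot control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding a hybrid EEG/EOG interface for shared robot control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridbci)
```

## The system being modelled

Severely motor-impaired users can operate assistive robots — a wearable
whole-arm exoskeleton or an external manipulator — through a hybrid
non-invasive interface: motor imagery attenuates the sensorimotor rhythm
(SMR, the 8–13 Hz oscillation over sensorimotor cortex), and this
event-related desynchronization (ERD) drives the opening and closing of a
hand mechanism, while horizontal oculoversions (HOV, lateral eye
movements picked up by EOG electrodes at the outer canthi) trigger the
robot's automatic reaching and retracting motions.  A five-state
finite-state machine supervises a drinking or pouring task — object
selection by gaze, reach, grasp-and-transport, place back, release — and
forbids concurrent triggering of arm and hand motions.

`hybridbci` implements this control chain end to end in software:
a synthetic-participant signal generator, the preprocessing and decoding
stages, the shared-control supervisor, the per-trial feasibility metrics,
and the nonparametric group statistics used to compare devices (exoskeleton
vs. manipulator) and control modes (cued "synchronous" vs. self-paced
"asynchronous").  Because no public recordings exist for this paradigm, the
generator is a first-class, tested component: every number the pipeline
produces can be traced back to a programmed ground truth.

## The decoding model

**ERD with the power method.**  The EEG derivation is a Hjorth-style
surface Laplacian centred on C3 (neighbours F3, T3, Cz, P3) followed by a
Butterworth band-pass.  Band power in the frequencies of interest (FOI,
the individually selected SMR centre frequency ± 1.5 Hz) is estimated per
500 ms window from an autoregressive model of order 100 fitted with the
Burg algorithm (a compiled implementation on the decoding hot path,
validated against `stats::ar.burg` to machine precision), and expressed
relative to a resting
reference value (RV):

$$\mathrm{ERD}(t) = \frac{P_{\mathrm{FOI}}(t) - RV}{RV} \times 100\,\%$$

Negative values denote desynchronization.  Calibration follows the study
protocol: 42 externally paced imagery trials of 5 s with 4 s inter-trial
intervals give the RV (mean FOI power over the rest intervals); a second
feedback run sets the detection threshold to the average elicited ERD
across trials.  Online, a control command is issued while the ERD trace
stays at or below the threshold (with a 200 ms dwell to debounce
single-window flickers).

**HOV detection.**  The bipolar derivation EOGR − EOGL (right-positive by
convention) is band-passed at 0.1–5 Hz; the detection threshold is 70% of
the mean absolute peak across 10 paced maximal oculoversions.  Online, an
event fires at the first threshold-crossing sample, with the direction
taken from the sign and a refractory period of 1.5 s.  The refractory
default exceeds the full saccade-and-return deflection because the
high-pass response of the return edge would otherwise read as an
opposite-direction oculoversion — with a left-HOV veto in the control
policy, that artifact would be destructive.

**Shared control.**  The supervisor ticks at 100 Hz.  Hand motions
accumulate *commanded* time only while the ERD signal is below threshold;
the grasp completes when the cumulative commanded time reaches the
mechanism's open/close time (1.5 s for the exoskeleton hand, 1.2 s for the
manipulator's gripper), so pauses stretch the elapsed — but never the
commanded — duration.  A left HOV during the post-selection confirmation
window vetoes the object selection.  Automatic segments (reach, transport,
return) run without user action; their durations (5 s each by default) are
placeholders, as robot motion times are hardware properties the pipeline
only represents through the device timing model.

## What the generator emulates — and what it does not

Each virtual participant is a parameter set: SMR centre frequency and
resting amplitude at C3, the fractional amplitude attenuation during
imagery (`erd_depth`), a 1/f background noise level, the peak bipolar HOV
amplitude, and per-condition reaction behaviour.  The SMR is an
amplitude-modulated sinusoid with 200 ms linear ERD ramps; neighbours
carry independent 1/f noise plus a common-mode component for the Laplacian
to remove; saccades are sigmoid steps (50 ms rise, ~1 s hold).  Reaction
latencies are log-normal (moment-matched mean/sd); with a per-condition
probability the user *pre-activates*, anticipating the cue by an
exponential lead.

Defaults are assumptions, not estimates of any patient population: no
subject-level spectra, amplitudes or ERD depths are publicly reported for
this paradigm.  We use 5 µV RMS SMR, depth 0.5, 2 µV noise, 250 µV HOV,
and per-condition latency means (1.3/1.1/1.9/1.5 s for
exoskeleton-synchronous/-asynchronous, manipulator-synchronous/
-asynchronous) loosely informed by the reaction-time ranges such systems
report; `pre_activation_prob` 0.3 with a 1.5 s mean lead.  The generator
does not attempt forward-modelled EEG (no head model or volume
conduction), blinks, EMG or nonstationary drifts — so green tests certify
the *decoding chain and bookkeeping*, not robustness to real-world
artifacts.

Two generator choices deserve emphasis:

* **Task-session ERD gain.**  The calibrated threshold is the *average*
  elicited ERD — by construction the middle of the calibration
  distribution, which a signal of identical depth crosses only half the
  time.  Operable online control therefore presumes deeper
  desynchronization during feedback-guided operation than the calibration
  average; task sessions default to 1.5× the calibration depth (capped at
  0.95 attenuation), which is also the operating point at which the
  detection-sensitivity properties are evaluated.
* **Closed-loop cue planning.**  The generator pre-computes each
  repetition's timeline with conservative nominal decoder delays, so the
  supervisor is always awaiting input before the planned cue.  In
  synchronous mode the cue reference for the metrics is the planned
  display time; in asynchronous mode, where no cue exists, it is the
  state-entry time.  Asynchronous timings therefore include the planning
  slack and the user's self-paced idle time, and pre-cue anticipation in
  that mode is modelled only for the gaze and ERD sub-tasks — the
  supervisor discards anticipatory saccades, so simulating them would
  merely stall the trial.

## Feasibility metrics

For every sub-task initialization, the **time to initialize (TTI)** is the
delay from the cue to the first decoder activation onset after it; if the
decoder was already active at the cue (or an activation onset preceded it
within the sub-task window), the negative **Pre-TTI** to the last prior
onset is reported instead.  Exactly one of the two exists per successful
initialization, and the pooled TTI+Pre-TTI is whichever exists.  The
normalized open/close time, $(t_{elapsed} - ERD_{dur}) / ERD_{dur}$, is 0
when the hand closed in exactly the mechanism time and measures the
stretch introduced by pauses otherwise.  A condition (device × mode) is
summarized by the median and [q25, q75] of its pooled TTI+Pre-TTI values
(linear-interpolation quantiles): control is *fluent* when the median is
below 3 s and *reliable* when the 75th percentile is below 5 s.  Both the
count of successful initializations and the attempted total are reported,
since either denominator is defensible for the 75%-of-sub-tasks
reliability reading.

## Group statistics

The unit of analysis is the per-participant median TTI+Pre-TTI per
condition (a per-participant reduction is required for paired tests even
though pooled medians are what condition summaries display).  The pipeline
is Shapiro–Wilk per condition (screening only), the Friedman test over
complete cases (listwise deletion — participant withdrawals and lost
sessions leave missing cells), then pairwise Wilcoxon signed-rank tests
with Pratt's zero method (zeros ranked, then dropped from the signed
sums; pairwise deletion), Holm–Bonferroni-corrected *within the family of
pairwise comparisons of one metric*.  Tests are two-sided.  The
Wilcoxon–Pratt p-value is exact — full sign-flip enumeration conditional
on the observed ranks — up to 12 non-zero differences, and a tie-corrected
normal approximation with continuity correction beyond.  Base R provides
Shapiro–Wilk, Friedman and the Holm adjustment; the Pratt variant is
implemented here because `wilcox.test` drops zeros *before* ranking
(the classical Wilcoxon treatment), which is a different statistic.

## Numerical choices

* **AR band power.**  The Burg-AR power spectral density is integrated
  over the FOI by an adaptive trapezoidal rule: starting from a 0.1 Hz
  grid, intervals are bisected until the local estimate converges, with a
  bounded work budget per window.  High-order AR spectra of
  near-sinusoidal signals concentrate power in resonances far narrower
  than any fixed grid; without refinement a spectral line loses most of
  its integrated power.  A perfectly noise-free sinusoid remains a
  documented pathological case (its line width underflows double
  precision); any realistic noise floor makes the integral exact to a few
  per mil.
* **Filter conditioning.**  The generic band-pass is a cascade of
  order-4 Butterworth high- and low-pass sections (zero-phase offline,
  causal online).  The ERD derivation instead uses order-2 sections: a
  steeper 30 Hz low-pass at 1 kHz leaves the signal so nearly band-limited
  that the order-100 Burg recursion becomes near-deterministic
  (prediction variance at numerical zero, degenerate spectra).  The softer
  roll-off keeps a broadband floor that conditions the fit — the analogue
  of the amplifier noise that real recordings always contain.
* **Windowing.**  500 ms windows (≥ AR order + 1 samples at 1 kHz),
  40 ms step online, non-overlapping during calibration; calibration
  statistics use only windows fully inside their annotated segment with a
  250 ms guard margin, because a causal window ending just after an epoch
  onset still covers mostly pre-onset data.
* **Degenerate calibrations.**  A participant without usable ERD contrast
  (calibrated threshold above −5%) is flagged rather than rejected — the
  decoder runs, but the calibration object carries `degenerate = TRUE`
  and a warning.
* **Determinism.**  All generators draw from seeds derived from a master
  seed via a Lehmer-style mix, and restore the caller's RNG state;
  `run_study()` re-run with the same configuration is byte-identical.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the full chain at reduced but
statistically adequate sizes chosen as a deliberate design point:
calibration recovery sweeps use 20 virtual participants at 24 calibration
trials each; detection operating points use 15-repetition sessions (30
sustained ERD epochs); latency recovery uses 20 repetitions (40
EEG-initialized sub-tasks) plus three 6-repetition sessions for
monotonicity; the determinism check runs a 2-participant, 2-condition,
1-repetition study twice.  The full study design (10 participants × 2
devices × 2 modes × 2 tasks × 10 repetitions, 42-trial calibrations) is
the default of `study_config()` and runs unchanged — only longer.

## Known limitations

* Absolute Burg band power is reliable only in the presence of a noise
  floor (see above); all pipeline quantities are power *ratios* and are
  insensitive to this.
* Asynchronous-mode timing is referenced to state entry, which
  structurally inflates its TTI relative to the synchronous mode; the two
  modes are not directly comparable in the simulator even though both are
  internally consistent.
* The 8–13 Hz centre-frequency search band is a parameter
  (`search_band`) rather than a fixed constant, since descriptions of the
  SMR band in this literature vary (8–12 Hz vs. 9–15 Hz); a single
  threshold serves both hand-opening and hand-closing imagery.
* EDF export is not provided; recordings serialize to headered CSV with a
  companion events table.
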