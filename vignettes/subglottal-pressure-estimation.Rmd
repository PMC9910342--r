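---
title: "Estimating subglottal pressure from neck-surface acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subglottal pressure from neck-surface acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpress)
```

## The problem

Subglottal pressure (Ps) -- the air pressure beneath the vocal folds that
drives phonation -- is a core aerodynamic measure of vocal function, but it
cannot be measured directly outside invasive settings. The standard indirect
estimate interrupts phonation with a bilabial /p/: during the lip occlusion
the intraoral pressure (IOP) equilibrates with Ps, so the peak of each IOP
plateau between vowels serves as a reference. This confines Ps to contrived
laboratory tasks. A miniature accelerometer (ACC) taped to the anterior neck
below the glottis senses tracheal-borne vibration during natural speech, and
its amplitude correlates strongly with Ps. `subpress` implements the full
chain that turns that correlation into a calibrated, person-specific Ps
estimator usable on daylong ambulatory recordings.

## Laboratory calibration

A calibration session records four channels at 20 kHz: microphone (Pa, 15 cm
from the lips), oral airflow (mL/s), IOP (cm H2O), and the ACC (cm/s^2,
recorded at 11,025 Hz and up-sampled). The participant produces repeated
/p/-vowel strings from loud to soft in three vowel contexts and three pitch
conditions, up to 20 syllables per breath.

Processing steps (`process_lab_session()`):

1. **Calibration lines.** Each raw voltage channel is mapped to physical
   units by an affine calibration (`fit_calibration_line()`,
   `apply_calibration()`), e.g. the five-point IOP calibration at 0, 5, 10,
   15, 20 cm H2O.
2. **Resampling and alignment.** The ACC stream is up-sampled by the exact
   rational factor 800/441 with a polyphase windowed-sinc filter
   (`resample_signal()`; each polyphase branch is normalized to unit sum so
   DC is preserved exactly) and aligned to the microphone by maximizing the
   cross-correlation within a +/- 1 s search (`align_acc_to_mic()`;
   acquisition offsets are sub-second, and integer-sample alignment is
   sufficient at these bandwidths).
3. **Segmentation.** Vowels are detected from a 10-ms RMS energy contour on
   the microphone: a segment is a run at least 80 ms long exceeding the
   noise floor (10th percentile of frame energy) by 20 dB. Segments shorter
   than 60 ms are flagged rather than deleted, because the middle-50-ms
   feature window must exist. IOP plateaus are detected per inter-vowel gap,
   one per contiguous supra-threshold run (the gap between two breath-group
   strings legitimately holds two plateaus); the plateau "peak" is the
   sample maximum, and a flatness metric (max - min over the 20 ms around
   the peak) is recorded for QC only.
4. **Reference Ps.** The reference for each vowel is the mean of the peak
   amplitudes of the plateaus immediately preceding and following it;
   one-sided segments are flagged and excluded from model fitting.

## Vocal-function measures

Per vowel segment (and per ambulatory frame), the package computes:

* **RMS** of the ACC middle 50 ms (cm/s^2);
* **SPL** `= 20 log10(MICrms / 20 uPa)` dB SPL at 15 cm (microphone in the
  laboratory; the log-log ACC-to-SPL mapping in the field);
* **f0** from the normalized autocorrelation in [70, 1000] Hz with parabolic
  interpolation. Peak choice matters: the package takes the shortest-lag
  peak within 5% of the highest peak in the band, so the period-T peak beats
  its own 2T/3T replicas (which sit only slightly lower because the biased
  autocorrelation estimate decays with lag) while spurious sub-period peaks
  from strong upper harmonics stay below it. The subglottal resonance can
  boost the second harmonic enough to pull the chosen peak to the half
  period; the estimate is then corrected to the double-lag peak when that
  peak is at least 0.25 of the chosen one *and exceeds it*. The second
  condition is essential: every periodic signal has a large replica peak at
  double the lag, so the 0.25 threshold alone would halve every f0. When no
  distinct double-lag peak exists, the reported subharmonic amplitude
  defaults to the main peak amplitude so that clean periodic frames are not
  rejected by the voicing criterion below.
* **CPP**: Hann window, FFT zero-padded to at least 8192 points, dB-magnitude
  spectrum, real cepstrum; CPP is the dB height of the cepstral peak in the
  2--14.3 ms quefrency band (70--500 Hz) above a regression line fit over
  that band. Exactly gain-invariant because a gain shift moves only the
  zero-quefrency bin.
* **Glottal airflow measures** from the inverse-filtered ACC (next section):
  ACFL (peak-to-peak flow, mL/s), MFDR (magnitude of the most negative flow
  derivative, L/s^2), OQ (open time / period, %), SQ (100 t_op / t_cp, %),
  H1-H2 (dB), HRF, and NAQ ((ACFL/MFDR)/period).

OQ and SQ require opening and closure instants that are not observable
directly: per cycle, the closure instant is the negative-derivative peak
(cycle anchor) and the opening instant is the rising crossing of the cycle
minimum plus 10% of the cycle peak-to-peak (the threshold is a tunable
parameter). A 10% threshold biases OQ down by a few points and SQ down by
~5-10% relative to the generative shape; closed-loop tests therefore use
the +/- 5-point (OQ) and +/- 15-point (SQ) tolerances. HRF is computed as
the conventional power ratio `10 log10(sum_{k=2..8} P_k / P_1)`; the
sum-of-log-magnitudes reading of the definition is available behind
`hrf_literal = TRUE`.

## Subglottal impedance-based inverse filtering (IBIF)

The ACC signal is a filtered version of the glottal airflow: tracheal
acoustics propagate the source pressure to the neck wall, and the skin
transmits it to the sensor as surface acceleration. The package models this
with five parameters -- skin inertance, resistance and stiffness (per-area
units), tracheal length, and sensor position below the glottis:

* the subglottal tract is a uniform lossy transmission line in 1-cm
  sections with a matched (lossy) termination toward the lungs, so the wall
  pressure at depth d is `Z0 * U_g * exp(-gamma d)`;
* the skin patch is a one-degree-of-freedom mass-spring-damper converting
  wall pressure to acceleration, `A = -w^2 P / (k - m w^2 + i r w)`;
* a fixed dimensionless wall-coupling efficiency scales lumen pressure to
  the sensed patch, calibrated so typical flows (ACFL ~300 mL/s) produce the
  1--30 cm/s^2 accelerations observed on real necks.

This is the minimal realization consistent with the five named parameters
and is documented as an approximation of the published transmission-line
model, not a reimplementation of it. Inversion divides the ACC spectrum by
this response with a Wiener-style floor at -40 dB of the in-band peak,
band-limits to 50--4000 Hz, and removes the mean (the ACC channel is
AC-coupled, so estimated flow is zero-mean by construction). The floor was
set at -40 dB rather than a more permissive -60 dB because the response
falls as w^2 below the skin resonance, and at -60 dB the corresponding
inversion gain amplifies segment-edge spectral leakage into visible sub-f0
artifacts; at -40 dB the round-trip waveform correlation exceeds 0.99
across the physiological parameter range with no measurable effect on the
time-domain measures.

In the laboratory, where simultaneous oral airflow is available, the five
parameters are fitted per participant by particle swarm optimization
(swarm 30, 200 iterations, inertia 0.72, cognitive/social weights 1.49,
seeded and deterministic). The objective is the mean-squared error between
the inverse-filtered ACC and the mean-subtracted, 50--1100 Hz band-passed
oral airflow after integer-lag alignment; matching waveforms rather than
derived features was chosen because the airflow waveform is the only
reference the laboratory setup provides. For ambulatory use a single
time-invariant IBIF model per participant is selected from the /a/ vowel
with the highest reference Ps in the comfortable pitch condition
(`select_ambulatory_ibif_segment()`).

Glottal measures are only trusted within physiological ranges
(`validity_filter()`): ACFL >= 1 mL/s, MFDR >= 1 L/s^2, OQ in 0--100%, and
f0 <= 500 Hz (inverse filtering is unreliable above that); violations carry
reason codes.

## The three estimators

* **Method 1** (`ps_method1()`): the empirical formula
  `Ps[kPa] = 0.14 + 0.06 (f0/foN)^2 + 10^((SPL - 88.5)/27.3)` with nominal
  f0 of 120 Hz (males) / 190 Hz (females), converted to cm H2O
  (1 kPa = 10.1972 cm H2O). Person-independent; no calibration needed.
* **Method 2** (`fit_method2()`): ordinary least squares
  `Ps = slope * ACCrms + intercept`, person-specific.
* **Method 3** (`fit_method3_stepwise()`, `crossvalidate_method3()`):
  forward stepwise multiple regression over the ten measures with a
  partial-F screening step (entry when the p-value is below alpha = 0.05;
  ties broken by larger F then canonical measure order), evaluated by
  five-fold cross-validation with seeded random folds (80/20 splits, fold
  sizes within one); the fold with the lowest test RMSE supplies the model
  used downstream. Forward-only entry matches the screening description;
  bidirectional elimination is available via `direction = "both"`.
  Predictions are not clipped; negative estimates are left to downstream QC.

With forward screening at alpha = 0.05 and ~8 uninformative candidates at
the stopping step, about a third of fits legitimately admit one decoy
(per-decoy rate ~ alpha); the tests assert the per-decoy rate, not
zero-decoy selection.

## Ambulatory processing

Daylong ACC streams (11,025 Hz) are cut into 50-ms non-overlapping frames
(trailing partial frame dropped). A frame is voiced iff all five features
fall inside the inclusive ranges: SPL 45--130 dB, f0 70--1000 Hz,
autocorrelation peak 0.60--1, subharmonic peak 0.25--1, low-to-high
spectral power ratio (below/above 2000 Hz) 22--50 dB. SPL comes from the
participant's log-log ACC-to-SPL mapping fitted on a descending-loudness
/a/ at the start of the day. Voiced frames are inverse filtered with the
fixed participant IBIF model, validity-filtered, and scored by the
participant's Method 3 (or Method 2) model. Daylong summaries report
phonation time, and per measure the mean, SD, skewness, 5th/95th
percentiles, and for Ps the histogram mode (0.5 cm H2O bins over 0--40 cm
H2O, ties to the lower bin -- the binning is a package choice; the source
statistic is just "mode"). Ps statistics are computed over voiced *valid*
frames only. Rolling profiles use 5-min windows at 30-s steps with
truncated edge windows flagged.

## The synthetic world

Human recordings of this kind are restricted, so the package ships
generators whose planted quantities every pipeline stage must recover --
this closed loop is the principal test harness.

* `lf_pulse_train()` builds glottal pulses with a quarter-sine rise and
  quarter-cosine fall (maximum negative slope at closure, like an
  abrupt-closure glottal pulse), zero flow in the closed phase, so OQ, SQ,
  ACFL and MFDR are known by construction.
* `synthesize_lab_session()` plants a linear Ps law
  `Ps = slope * ACCrms + intercept (+ oq_coef * (OQ - 60))`, brackets each
  vowel with trapezoidal IOP plateaus (80-ms flat top) whose peaks average
  to the planted Ps, forward-filters the flow through the participant's
  true IBIF model, and scales so the middle-50-ms ACC RMS matches the law
  exactly. Plateau noise is modeled as a slow per-plateau offset (SD =
  `iop_sigma`) plus a small smooth ripple: per-sample white noise would
  bias the sample-max peak upward by ~3 sigma, which real breath-pressure
  wobble does not. The microphone is a two-formant rendering of the flow
  derivative (/a/ 700/1200, /i/ 300/2300, /u/ 350/800 Hz) -- enough for
  energy segmentation and SPL, with no claim of intelligibility. Defaults:
  Ps sweeps 16 down to 4 cm H2O (laboratory elicitation typically tops out
  at 16--18 cm H2O), plateau noise 0.3 cm H2O, 40 dB ACC SNR, loudest vowel
  92 dB SPL.
* Voiced synthesis always includes low-level high-passed aspiration noise
  (-35 dB relative to the voiced RMS). This is physiological turbulence,
  not measurement noise: without any energy above 2 kHz the low-to-high
  spectral ratio of a clean pulse train exceeds the 50-dB VAD ceiling and
  every synthetic voiced frame would be rejected as electrical-hum-like.
* `synthesize_day()` lays voiced/unvoiced spans on the 50-ms frame grid
  (so truth flags are crisp), drifts loudness (+/- 8 dB) and pitch
  (+/- 20%) with a slow sinusoid plus bounded random walk, sets per-frame
  gains so the planted Ps law holds exactly frame by frame, and fills
  unvoiced spans with broadband noise near 35 dB SPL equivalent -- below
  the VAD floor.

What a green closed-loop test does **not** establish: fidelity to
pathological voice distributions, real skin/sensor variability, motion
artifacts beyond what the five VAD criteria describe, or the clinical
group statistics of the source populations. The generators expose the
knobs but claim no clinical fidelity.

## Numerical choices and degenerate inputs

* FFT-domain zero-phase band-passes with raised-cosine transitions are used
  throughout (no IIR phase distortion on waveform-shape measures).
* Autocorrelation peaks and harmonic frequencies are refined by parabolic
  interpolation / local search; harmonics above Nyquist are skipped with a
  flag.
* Zero-energy windows raise explicit errors (undefined SPL, undefined
  alignment); white-noise frames return an unvoiced signal rather than an
  f0; degenerate regressions (constant predictors) raise errors; PSO
  non-convergence returns the best-so-far parameters with a warning.
* All generator and fitting randomness is seeded, and seeded code restores
  the caller's RNG state.

## Known limitations

* The IBIF realization approximates the published subglottal model; fitted
  parameter values are not comparable to published ones even though the
  transfer shape and the inversion behave correctly (the (length, position)
  pair is weakly identified -- the objective is nearly flat along it).
* Methods 1 and 2 RMSEs are evaluated on the same laboratory segments used
  to fit Method 2, mirroring the source protocol; only Method 3 carries a
  held-out error.
* The two-way ANOVA battery over groups and methods is out of scope; the
  comparison harness exports a tidy per-participant table instead.
* The neural-network estimator from the source line of work (two fully
  connected hidden layers of four neurons, trained on 13,000 synthesized
  vowels from a triangular body-cover model) is deliberately not
  implemented: its training corpus and voice-production model are external
  to this package's scope.
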