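---
title: "Methods: chirp-percussion analysis of lung sound transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chirp-percussion analysis of lung sound transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpscope)
```

## The measurement model

Auscultatory percussion introduces a known sound at one chest site and
records what arrives at another; the transmission path through the lung
determines how much arrives. Aerated lung is a strong acoustic mismatch
and attenuates; consolidated or fluid-filled lung couples sound much more
efficiently in some bands and, at the recorded posterior sites and
frequencies used here, presents as an overall intensity *loss* of the
transmitted percussive input relative to healthy lung. The package's core
measurement is therefore the transmitted intensity of a linear 100–1000 Hz
chirp as a function of its instantaneous frequency, and its core contrast
is the healthy-minus-pathological group difference of that curve in dB.

The analysis chain assumes: a mono 4 kHz recording time-aligned with the
14 s chirp; an approximately linear, time-invariant transmission path per
recording; and measurement noise well below the transmitted chirp (the
moving ±20 Hz band average rejects most broadband noise, but a noise floor
above the attenuated chirp bounds the measurable attenuation).

## Signal-processing choices

* **Chirp synthesis.** The phase is the exact integral of the linear
  frequency ramp (quadratic in time). A stepped-frequency approximation
  would smear instantaneous frequency at exactly the scale the ±20 Hz
  band tracking depends on.
* **Spectrogram.** 256-point Hamming-windowed blocks, magnitude of the
  one-sided FFT. The frame count for a 56,000-sample recording is fixed at
  109 evenly spaced frames; a hop of 512 samples is the only integer hop
  that achieves this with a 256-point window, so blocks are
  non-overlapping with a 256-sample gap. Nothing downstream depends on the
  skipped samples: the chirp moves only ~32 Hz per hop, well inside the
  tracked band. The Hamming window uses the symmetric α = 0.54 convention.
* **Band tracking.** Bins whose center frequency lies within the *closed*
  ±20 Hz interval around the chirp frequency at the frame center are
  averaged; at 15.625 Hz spacing this is 2–3 bins. Magnitudes (not powers)
  are averaged and then converted as 20·log10, matching the "magnitude in
  dB" reading; a power-domain variant would shift all curves by a constant
  and leave every group difference unchanged.
* **dB floor.** Magnitudes are clamped at 1e-12 before the log so silent
  inputs stay finite. The floor counter is exposed as an attribute and the
  test suite asserts it never fires on default synthetic cohorts.
* **Averaging order.** Profiles are converted to dB per recording first,
  then averaged with SEM = sample SD/√n per frequency. dB-domain averaging
  yields symmetric error bands; linear-domain averaging (mean of band
  magnitudes, delta-method SEM) is available via
  `group_average_curve(domain = "linear")`.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the *statistical structure* of the study
conditions: 133 healthy and 12 ACS observations; six posterior sites with
pathology expressed at the basal pair; between-subject variability as a
flat gain offset (SD 2 dB) plus a smooth spline wiggle through 8 knots
(SD 1 dB), chosen so the healthy group's SEM band is visibly
non-degenerate; ACS extra attenuation with per-recording mean drawn
uniformly from 12–16 dB — so cohort averages land in the 12–15 dB range —
mean-centered smooth variation (SD 1.5 dB), and a hard 5 dB floor at every
frequency; additive white Gaussian noise at −40 dB re the chirp amplitude.
Healthy observations are assigned round-robin across six-site subjects;
ACS subjects contribute at the affected sites only, so the observation
counts are exact by construction.

It does **not** emulate: physiological sounds (heart, breath, bowel),
non-stationary ambient noise, stethoscope transfer functions or placement
variability, airway-tree or parenchymal wave propagation (the transmission
model is phenomenological — a frequency-dependent loss applied as a
zero-phase spectral multiply), or chest-wall habitus effects beyond a flat
gain. Passing tests on this cohort therefore demonstrate that the
*pipeline* is correct and that the claimed attenuation structure is
recoverable and classifiable — not that real recordings of this protocol
would classify equally well. The uncomplicated-VOC clinical category is
generated from the healthy model and complicated VOC from the ACS-like
model, mirroring their observed acoustic behavior.

The Gaussian noise model is a stand-in: no noise characterization of real
recordings is available. The −40 dB default keeps the noise floor an order
of magnitude below even a 20 dB-attenuated chirp, which is what makes the
±1 dB parameter-recovery guarantee attainable.

One protocol ambiguity is resolved by configuration: sources describing
this protocol give the sweep start as either 20 Hz or 100 Hz. The default
is `f_start = 100`; it is a `chirp_spec()` field, and every stage consumes
the spec rather than hard-coding the span.

## Features

The 20 features split by representation: distributional statistics (mean,
median, SD, q25/q50/q75, Fisher skewness, excess kurtosis) summarize the
dB intensity profile — the transmission curve itself — while the 12 MFCCs
summarize the waveform's spectral envelope. q50 duplicates the median by
construction and is retained so the count is exactly 20 (1+1+1+3+1+1+12).
MFCC parameters are the common speech-processing defaults (25 ms/10 ms
Hamming frames, 26 mel filters over 0–2000 Hz, orthonormal DCT-II, c0
excluded, mean-pooled over frames), all configurable. Excluding c0 makes
the MFCC block exactly invariant to global gain, which is desirable here:
overall level is already captured, more interpretably, by the profile
statistics. Skewness and kurtosis use the uncorrected Fisher definitions
with a 0-for-constant convention so degenerate profiles stay finite.

## Classifier

RUSBoost addresses the 133:12 imbalance by undersampling the majority
class to a 1:1 ratio each round (weighted draw without replacement, all
minority observations kept) while boosting recovers the information the
undersampling discards: the weighted error that drives the learner weight
and the reweighting is computed on the *full* training set. The two-class
AdaBoost update is used; for binary labels it is equivalent to the
original multi-class pseudo-loss formulation. Defaults — 30 rounds,
learning rate 0.1, trees pruned to ≤ 20 splits — mirror the conventional
defaults of boosted-tree ensembles of this kind. Rounds with weighted
error ≥ 0.5 are resampled (up to 10 times) before boosting stops; a round
with zero error keeps its learner with the error clamped to 1e-10 and
stops early.

Trees are `rpart` fits grown with `cp = 0` and pruned back to at most 20
splits via the complexity table, the closest faithful expression of a
max-split constraint in that implementation.

Evaluation is stratified 5-fold cross-validation: with only 12 minority
observations, stratification (2–3 per fold) is the only workable design,
and all out-of-fold predictions are pooled into a single confusion matrix
and ROC so minority-class rates are well-defined. Reported metrics include
accuracy, PPV, TPR and FPR side by side, since "positive predictive
accuracy" is ambiguous between overall accuracy and PPV. The ROC is a
threshold sweep over unique scores with simultaneous inclusion of ties;
its trapezoid AUC equals the Mann–Whitney statistic with tie half-credit,
and the test suite verifies that equality by brute-force pair enumeration.
Ties at the 0.5 decision threshold resolve to the ACS class, the costlier
class to miss.

## Labeling and exclusion rules

`classify_subject()` encodes the clinical pathway: infiltrate-bearing
imaging plus fever or respiratory symptoms is ACS; an infiltrate or
consolidation without the full symptom picture is complicated VOC; a VOC
admission with clean imaging and no scarring is uncomplicated VOC and
eligible for the healthy pool; scarring never yields a healthy label. The
symptom requirement is operationalized as a disjunction (fever OR
respiratory symptoms) with a stricter conjunction available via
`symptom_rule = "and"`, since the clinical definition lists accompanying
symptoms without a minimal rule. Retrospective reclassification (a VOC
admission later diagnosed as ACS) is supported through an optional
follow-up label that overrides the pathway; off by default.
`apply_exclusions()` drops BMI strictly above 30 (BMI = 30 retained) and
any non-Eko device, logging one reason per subject; it is order-preserving
and idempotent. Findings map to acoustic effect classes: pleural effusion,
consolidation, infiltrate and scarring attenuate; ground-glass opacity is
mixed (it can be predominantly interstitial or more consolidative);
everything else in the vocabulary has no expected effect. The lists are
arguments, not constants.

## Numerical and degenerate-input behavior

* `apply_transmission` is a zero-phase full-length FFT multiply with
  constant extrapolation of the attenuation beyond the profile grid; a
  flat 0 dB profile reproduces the input to ~1e-15, and a profile not
  covering the chirp span is a hard error rather than an extrapolation.
* WAV interchange is PCM 16-bit; the float path is used internally so
  quantization enters only at write time. Round-tripping perturbs
  intensity profiles by well under 0.1 dB.
* Group curves require n ≥ 2 (SEM undefined at n = 1 is an error, not 0);
  mismatched frequency grids are alignment errors everywhere.
* Noise addition clips to [−1, 1] with a warning; `noise_db = -Inf` is the
  documented off switch.
* All seeded operations save and restore the caller's RNG state, so
  determinism contracts are side-effect free.

## Problem sizes in the test suite

Unit and property tests run on scaled-down cohorts (about 20–30
observations) chosen so every contract — determinism, stratification,
parameter recovery, permutation-null leakage checks, noise monotonicity —
is exercised in seconds; the full 145-observation default cohort is
generated once per run for the structural-count and cross-validation
checks. The permutation-null and monotonicity properties use the
scaled-down cohorts; their assertions are unchanged from the full-size
statement.

## Known limitations

The transmission model is phenomenological, the noise model is white and
Gaussian, and the synthetic classes are more separable than clinical
reality (the generator's ≥ 5 dB floor guarantees separation that real
cohorts only exhibit on average). Classifier metrics on synthetic cohorts
are therefore upper bounds on, not estimates of, clinical performance.
Cross-device calibration (e.g. between stethoscope models) is explicitly
out of scope — foreign devices are excluded, not harmonized — and no
free-text EMR processing is attempted: labeling consumes structured flags.
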