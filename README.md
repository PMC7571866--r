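# chirpscope

Chirp-based auscultatory percussion analysis for detecting lung
consolidation, aimed at screening for acute chest syndrome (ACS) in sickle
cell disease.

ACS is clinically defined by a new pulmonary infiltrate on chest imaging
with accompanying fever or respiratory symptoms, and is the leading cause
of death in sickle cell disease. Auscultatory percussion offers a
bedside-compatible acoustic alternative to imaging: a vibratory chirp — a
sinusoid sweeping linearly from 100 to 1000 Hz over 14 s — is introduced at
the sternum and recorded at six posterior chest sites (apex, middle, basal;
left and right) with an electronic stethoscope at 4 kHz. Consolidated or
fluid-filled lung transmits the chirp at markedly lower intensity than
aerated lung, and that attenuation is measurable and classifiable.

`chirpscope` is for researchers developing or evaluating this kind of
acoustic screening pipeline. Because clinical recordings of this type are
not public, the package pairs the analysis chain with a synthetic cohort
generator whose statistical structure matches the published study
conditions, so every stage is testable end to end.

## The method

For a recording \(x\) the pipeline computes:

1. **Spectrogram** — Hamming-windowed 256-point FFT blocks, hop 512
   samples, giving exactly 109 evenly spaced frames over 14 s at 4 kHz
   (129 one-sided bins, 15.625 Hz spacing).
2. **Chirp-tracking intensity profile** — for each frame, the mean
   spectrogram magnitude over bins within ±20 Hz of the instantaneous
   chirp frequency \(f(t) = f_0 + (f_1 - f_0)\,t/T\), converted to dB:
   \(I(f) = 20\log_{10}\bar{m}(f)\). Group curves report the per-frequency
   mean ± SEM (sample SD/√n) across recordings; the healthy-minus-ACS
   difference \(\Delta(f)\) is summarized by its mean and minimum over the
   sweep.
3. **20 features** — mean, median, SD, quartiles (q25/q50/q75), Fisher
   skewness and excess kurtosis of the dB profile, plus the per-frame mean
   of MFCC coefficients 1–12 of the waveform (25 ms/10 ms Hamming frames,
   26-filter mel bank over 0–2 kHz, orthonormal DCT-II, gain-carrying c0
   excluded).
4. **RUSBoost classification** — AdaBoost-style boosting where each round
   fits a depth-limited tree (≤ 20 splits) on a class-balanced random
   undersample of the majority class, with weighted error evaluated on the
   full training set: \(\alpha_t = \nu \ln\frac{1-\epsilon_t}{\epsilon_t}\),
   correct weights scaled by \(\epsilon_t/(1-\epsilon_t)\) and
   renormalized. Evaluation is stratified 5-fold cross-validation with
   pooled out-of-fold confusion matrix, accuracy, PPV, TPR/FPR and a
   threshold-sweep ROC/AUC (equal to Mann–Whitney with tie half-credit).

The synthetic generator produces a 133 healthy / 12 ACS observation cohort
(145 total): per-subject transmission = flat gain offset (SD 2 dB) + smooth
spline wiggle; ACS recordings get extra attenuation with mean drawn from
12–16 dB, floored at 5 dB at every frequency; Gaussian measurement noise at
−40 dB re the chirp amplitude.

## Worked example

```r
library(chirpscope)

cohort   <- generate_cohort(cohort_config())          # 133 healthy + 12 ACS
profiles <- lapply(cohort$recordings, intensity_profile)
labs     <- cohort$metadata$true_label

healthy <- group_average_curve(profiles[labs == "healthy"])
acs     <- group_average_curve(profiles[labs == "acs"])
d       <- group_difference(healthy, acs)
sprintf("mean diff %.1f dB, min diff %.1f dB", d$mean_db, d$min_db)
#> "mean diff 14.1 dB, min diff 12.8 dB"

feats <- cohort_feature_table(cohort)                 # 145 x 20 features
cv <- stratified_cv(feats[, FEATURE_NAMES], feats$label, k = 5, seed = 43)
cv
#> Stratified 5-fold CV (pooled out-of-fold metrics)
#>          predicted
#> truth     healthy acs
#>   healthy     133   0
#>   acs           0  12
#> accuracy 1.000 | PPV 1.000 | TPR 1.000 | FPR 0.000 | AUC 1.000
```

The 14.1 dB mean group difference recovers the generator's injected mean
extra attenuation (14.7 dB for this seed) to within the between-subject
gain variability; the minimum difference stays above the 5 dB floor plus
baseline. On this synthetic cohort the classes are nearly separable, so
cross-validated classification is essentially perfect — far above the
imbalanced majority-vote baseline of 133/145 = 91.7% and, crucially, with
full recall of the rare ACS class.

`run_pipeline(run_config())` executes the whole chain and writes WAVs,
metadata, profile and group-curve CSVs, plots, the feature table, a
`results.json` and a plain-text report; `inst/scripts/chirpscope` wraps it
as a command-line tool with `simulate`, `analyze` and `run` subcommands.

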