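Package: chirpscope
Title: Chirp-Based Auscultatory Percussion Analysis for Lung Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing auscultatory-percussion recordings in which a
    linear frequency chirp is introduced at the sternum and recorded at
    posterior chest sites, as used to screen for acute-chest-syndrome-like
    lung consolidation in sickle cell disease. Provides a synthetic cohort
    generator with parametric frequency-dependent chest transmission models,
    chirp-tracking spectrogram band-average intensity profiles with group
    mean and standard-error curves, a 20-dimensional acoustic feature
    extractor (distributional statistics of the intensity profile plus 12
    Mel-frequency cepstral coefficients), a random-undersampling boosted
    tree ensemble (RUSBoost) for the strongly imbalanced healthy-versus-ACS
    classification task with stratified cross-validation and ROC/AUC
    metrics, and electronic-medical-record-style cohort labeling and
    exclusion rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
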