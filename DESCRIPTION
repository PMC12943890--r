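Package: mtaim
Title: Movement Classification from Wearable Strain-Sensor Time Series with
    Generative Augmentation
Version: 0.1.0
Authors@R: person("MT-AIM", "Maintainers", email = "maintainers@mtaim.dev",
    role = c("aut", "cre"))
Description: A classification pipeline for six low-back movements measured by a
    six-channel wearable piezoresistive strain sensor array ("Motion Tape").
    Provides a seeded cohort simulator emulating the statistical structure of
    such recordings (movement-specific strain templates, paired lumbar Euler-
    angle kinematics, subject variability, noise, spikes, drift); the raw-
    resistance preprocessing chain (baseline normalization, Hampel outlier
    filtering, noisy-trial exclusion, alignment and per-movement-trial min-max
    scaling); frequency-domain (DTFT magnitude) and generated-kinematics
    feature augmentation; conditional generative models (class-conditional
    C-VAE and DDPM-style diffusion, plus a strain-conditioned kinematics
    translator with a transformer-encoder condition path) built on a small
    reverse-mode autodiff engine; generative-quality metrics (empirical 1-D
    Wasserstein distance and discrete Frechet time-series distance); CNN-LSTM,
    transformer and gradient-boosted-tree classification heads; and the
    evaluation protocol (stratified and leave-one-subject-out splits, repeated
    ablation grid, subject-identifiability control, PCA projection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
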