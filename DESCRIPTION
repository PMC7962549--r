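Package: morphotrack
Title: Prognostic AI Monitoring of Longitudinal Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable chest-CT registration with a two-stage
    convolutional network (affine alignment followed by U-Net deformable
    registration), whose latent feature maps are pooled into order-invariant
    statistics over a scan pair and fed to a random-forest classifier that
    predicts 1-year overall survival from the date of the later scan.
    Includes occlusion-sensitivity prognostic heatmaps, a round-trip landmark
    metric for registration quality, a synthetic longitudinal phantom cohort
    generator with known lesion dynamics and simulated survival, and survival
    statistics (Kaplan-Meier, log-rank, Cox, bootstrap AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    randomForest,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
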