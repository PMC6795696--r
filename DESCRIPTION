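Package: habitatmap
Title: Tumor Habitat Mapping from Multi-Parametric MRI
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Voxel-wise tissue classification of soft-tissue sarcoma from
    co-aligned multi-parametric MRI (apparent diffusion coefficient, Dixon
    fat-fraction and contrast enhancement-fraction maps). Provides parameter-map
    computation and normalization, training-set assembly from labeled regions of
    interest including a synthesized uniform "novelty" class, a native Gaussian
    naive-Bayes voxel classifier plus pluggable alternative families, exhaustive
    one-ROI-per-class cross-validation for hyperparameter selection, Markov
    random field label de-noising by iterated conditional modes, per-habitat
    volume and ADC quantification with Spie-chart geometry, and a synthetic
    phantom generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    e1071,
    randomForest,
    nnet,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
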