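Package: cognivq
Title: Prototype-Based Classification of Cognitive Profiles with Privileged
    Neuroimaging Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generalized Matrix Learning Vector Quantization (GMLVQ)
    classifiers for discriminating patient and control cognitive profiles,
    with support for learning using privileged information: an adaptive
    Mahalanobis metric in the cognitive-score space is shaped by
    similarity constraints derived from fMRI-based features via
    information-theoretic metric learning (ITML). Includes fMRI feature
    extraction (percent signal change and discriminative
    connectivity-graph features via 2D linear discriminant analysis on
    kernel-reduced voxel correlation matrices), class-imbalance
    downsampling ensembles with majority voting, metric-tensor relevance
    analysis, and a seeded synthetic cohort generator for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
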