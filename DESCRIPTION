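Package: semdecode
Title: Zero-Shot Semantic Decoding and Searchlight RSA for fMRI Activation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping trial-level fMRI activation patterns into
    corpus-derived word-embedding semantic spaces and back. Implements
    feature-sum semantic coordinate models for clue-based stimulus designs,
    voxel stability selection, regularized (ridge) linear decoders evaluated
    with zero-shot leave-two-out pairwise classification, permutation nulls for
    chance calibration, region-of-interest decoding, and a spherical
    searchlight representational similarity analysis with nonparametric
    sign-flip group inference (pseudo-t, family-wise error control by the
    maximum statistic). A forward-model simulator generates semantic spaces,
    feature norms, clue-triplet designs and voxel beta patterns with known
    ground truth so the full pipeline can be exercised and validated without
    access-restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
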