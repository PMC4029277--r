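Package: cpisketch
Title: Scalable Compound-Protein Interaction Prediction with Minwise-Hashing Sketches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts compound-protein interactions from binary chemical
    substructure and protein domain fingerprints. Pair features are the
    tensor product of the two fingerprints; these sparse, very
    high-dimensional vectors are compressed into compact fingerprints by
    minwise hashing followed by an additional hashing stage with a known
    collision law, then classified with L1- or L2-regularized hinge-loss
    linear models. Learned weights on compact coordinates can be mapped back
    to substructure-domain features for interpretation. Includes pair-wise
    and block-wise cross-validation, negative sampling, AUC scoring, and a
    synthetic data generator with a planted sparse interaction model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
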