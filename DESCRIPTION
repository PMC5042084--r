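Package: metacontact
Title: Residue-Residue Contact Prediction from Sequence Covariation with a
    Two-Stage Neural-Network Meta-Predictor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts residue-residue contacts in proteins from multiple
    sequence alignments. Implements mutual information (raw and
    average-product-corrected), mean-field direct coupling analysis, sparse
    inverse covariance estimation (graphical lasso), and pseudolikelihood
    Potts-model inference, and combines them with classical alignment-derived
    features in a two-stage neural-network meta-predictor that modulates
    between covariation and classical signal by alignment depth. Includes
    effective-sequence-count accounting by 62 percent identity clustering, a
    Potts-model family simulator with known contact topologies for training
    and benchmarking, CASP-style top-L/5 precision evaluation with RR file
    input/output, and square-well contact restraint energies for scoring
    3D coordinate models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    bio3d
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
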