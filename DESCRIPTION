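Package: distrank
Title: Distance-Based Quality Assessment, Ranking and Combination of Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the accuracy of candidate protein tertiary
    structure models (decoys) from predicted inter-residue distance and contact
    maps, without the native structure. Implements Ca-level structure input and
    geometry diagnostics, GDT-TS and TM-score superposition metrics,
    distance-map matching features (SSIM, PSNR, GIST-style descriptors, RMSE,
    recall/precision, perceptual hash, Pearson correlation, ORB-style keypoint
    matching), contact matching scores, pairwise-consensus and rank-average
    scoring, a two-level stacked quality-assessment regressor, alignment-driven
    domain parsing, consensus model combination with an acceptance gate and
    TM-score-based region splicing, CASP-style evaluation statistics (ranking
    loss, Z-scores, skewness, Neff, good-model fraction), and a deterministic
    synthetic-fixture generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    EBImage,
    ggplot2,
    jsonlite,
    nnet,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
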