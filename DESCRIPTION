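Package: virann
Title: Phage Virion Structural Protein Classification with Neural-Network Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacteriophage proteins into ten virion structural
    classes (major/minor capsid, portal, head-tail joining, collar, major/minor
    tail, tail sheath, tail fiber, baseplate) plus a background "others" class
    from sequence composition alone. Implements k-mer composition features over
    the amino-acid and a reduced 7-group side-chain alphabet, physicochemical
    descriptors, a homology-aware cluster-expansion train/validation/test
    split, a ten-member multilayer-perceptron ensemble trained by 10-fold
    cross-validation, summed-softmax ensemble scoring with per-class
    score-to-confidence calibration, and full evaluation machinery
    (per-class and averaged precision/recall/F1, confusion matrices, ROC,
    low-score filtering). A synthetic corpus generator with controlled
    homology structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
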