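Package: foldcep
Title: Protein Fold Classification Under Structure-Space Continuity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Likelihood-style assignment of query protein domains to existing
    folds (CATH topology level or SCOP fold level) that accounts for fold-space
    continuity. Implements the cumulative empirical probability (CEP)
    classifier, its Bayesian counterpart C3P backed by a reversible-jump MCMC
    Gaussian mixture fit to within-fold TM_max scores, TM-score computation
    under local and global length normalization for supplied residue
    correspondences, repeated hold-out classification experiments, evaluation
    summaries (reclassification rates, fold attraction, heterogeneity
    correlations), and a synthetic fold-universe generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
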