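Package: foldscape
Title: Fold-Space Analysis of Compact Polypeptide Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the space of compact folds accessible to short
    polypeptide chains. Provides multi-model PDB ingestion of conformational
    ensembles, secondary-structure assignment from backbone hydrogen-bond
    geometry, TM-score structural alignment with target-length normalization,
    contact-order and contact-locality descriptors, trajectory frame
    filtering, greedy independent-fold clustering, discovery-curve
    extrapolation of the total fold count, re-discovery statistics, and
    deterministic generators of protein-like synthetic structures with known
    fold ground truth.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
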