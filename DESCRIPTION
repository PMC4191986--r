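Package: caprese
Title: Probability-Raising Reconstruction of Cancer Progression Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tree and forest models of cumulative progression
    (such as the accumulation of genomic alterations in cancer) from
    cross-sectional binary genotype data. Implements the CAPRESE algorithm,
    which scores candidate causal edges with Suppes probability raising
    combined with a shrinkage-like estimator and separates independent
    progression paths with a correlation-based filter, together with the
    correlation-weight oncotree baseline reconstructed by maximum-weight
    arborescence. Includes generators for synthetic cross-sectional data
    sampled from tree-induced distributions under uniform or asymmetric
    noise, structural evaluation via Zhang-Shasha tree edit distance and
    Hamming distance, and parametric/non-parametric bootstrap confidence
    estimation for reconstructed progressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
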