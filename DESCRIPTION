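Package: scfvdesign
Title: Bayesian In Silico Design of Antibody (scFv) Variant Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for machine-learning-guided affinity
    maturation of single-chain variable fragments (scFvs). Trains
    uncertainty-aware sequence-to-affinity surrogate models (a multi-encoder
    regression ensemble and a PCA + Gaussian-process model) on replicated,
    detection-limit-censored mutagenesis assay data, converts predictions into
    a Bayesian fitness landscape (the posterior probability that a variant
    binds more strongly than a threshold), and samples candidate libraries
    with hill-climb, genetic-algorithm and Gibbs strategies alongside
    directed-evolution baselines (random mutants, position-specific score
    matrix). Includes a configurable synthetic ground-truth landscape and
    assay simulator for desk-scale benchmarking, library evaluation metrics
    (percent success, diversity, fold improvement, rank agreement, 2-D
    embedding), and sequence-level developability descriptors (isoelectric
    point, hydropathy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
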