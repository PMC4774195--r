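Package: auxnet
Title: Block-Model Clustering of Two-Way Yeast Two-Hybrid Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns two-way, two-reporter yeast-2-hybrid screens of the
    Arabidopsis auxin signalling regulators (ARF and Aux/IAA families) into
    binary and valued protein-interaction networks, and clusters them with
    mixture models for random graphs: Bernoulli block models for binary
    graphs, Gaussian block models for valued graphs, and linear-regression
    mixtures in which per-cluster-pair edge means depend on dimerisation
    sequence dissimilarities.  Models are fitted by variational EM with a
    fixed-point E-step and compared with the integrated completed likelihood
    (ICL) criterion.  Includes rank-based standardization of ordinal (X-Gal)
    and ratio (HIS3) reporter outputs, reporter thresholding and decision
    rules for binarization, a PHYLIP square distance-matrix reader for
    sequence covariates, connectivity-profile cluster diagnostics, partition
    comparison by optimal label matching, and seeded simulators for every
    stage of the pipeline.
License: MIT
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
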