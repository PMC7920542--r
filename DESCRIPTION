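Package: cortconn
Title: Construction and Analysis of Whole-Cortex Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing parcellated structural
    connectomes from probabilistic-tractography streamline counts.
    Implements fractional-scaling normalization, symmetrization and log
    transformation of connection weights; exponential distance-decay
    modelling with candidate-model comparison; interindividual
    variability statistics; bootstrap laterality and contralateral-
    homolog tests; cortical-hierarchy (myelination) analyses; binary
    graph-theoretic metrics with null-model normalization and density
    sweeps; intermodal comparison against evoked-potential and
    resting-state functional connectivity including two-component
    Gaussian-mixture mode splitting; and a synthetic connectome
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    mclust,
    igraph,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
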