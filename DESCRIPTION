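Package: drugnet
Title: Drug Target Deconvolution and Network-Diffusion Scoring for
    Chemical Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns competition-pulldown spectral-count tables from
    chemical proteomics into per-drug target profiles (specificity
    gating, abundance scoring, kinase weighting, cross-cell-type
    merging, Kolmogorov-Smirnov specificity statistics), propagates
    target and disease-gene signals over a protein-protein interaction
    network by random walk with restart, and correlates the resulting
    drug-treatment and disease network models into deletion-weighted
    scores normalized against null disease gene sets.  Includes a
    synthetic-data generator that emulates the statistical structure of
    competition pulldowns and copy-number-derived disease models so the
    whole pipeline can be exercised and benchmarked without proprietary
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
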