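Package: lipogate
Title: Lipid-Operated Gating Analysis for Inwardly Rectifying Potassium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how membrane lipid acyl tails
    operate the hydrophobic leucine collar gate of a Kir (inwardly rectifying
    potassium) channel. Provides trajectory input/output for multi-model PDB
    and tabular coordinate formats; pore radius profiling; collar aperture
    geometry (diagonal couplets, symmetrization, cross-sectional area);
    protein-lipid contact censuses and head-group density maps; ion permeation
    event detection and hydration statistics; a native weighted histogram
    analysis method (WHAM) estimator with Bayesian-bootstrap uncertainty for
    umbrella-sampling free-energy profiles; hidden Markov model idealization
    of three-level single-channel current recordings with burst-wise open
    probability; and liposome flux-assay normalization, first-order decay
    fitting and Dunnett-adjusted group comparisons. Seeded synthetic-data
    generators emulate the statistical structure of each input so the whole
    pipeline can be exercised and validated without molecular dynamics or
    patch-clamp data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
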