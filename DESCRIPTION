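Package: cropqtl
Title: Analysis of Pooled Single-Cell CRISPRi Screens of Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, tested pipeline for CROP-seq style pooled
    CRISPRi screens that map non-coding regulatory elements to the genes
    they control in single cells. Provides probabilistic guide-RNA to cell
    assignment by a binomial test against plasmid-library proportions,
    median-absolute-deviation quality control, a two-part (hurdle) model
    for per-guide differential expression against non-targeting controls,
    Fisher combination of guide-level evidence into target-level
    element-to-gene calls with confidence tiers, and null-calibration
    diagnostics based on pseudo-targets built from non-targeting guides.
    A synthetic screen generator with known ground truth (low-MOI
    transduction, ambient guide noise, negative-binomial expression with
    per-target knockdowns, batch structure) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
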