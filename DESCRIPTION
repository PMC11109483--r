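Package: ubinteract
Title: Ubiquitin Chain Interactor Profiling and Steady-State Affinity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of ubiquitin chain pulldown interactome experiments:
    reading MaxQuant-style protein-group quantification tables, preprocessing
    (flag filtering, dropout-sample removal, valid-value filtering, log2
    median normalization, left-censored downshift imputation), empirical-Bayes
    moderated t and F statistics with Benjamini-Hochberg adjustment, a
    two-pass bead-control enrichment prefilter, chain linkage/length/branch
    specificity classification, Fisher annotation enrichment, and surface
    plasmon resonance steady-state affinity fitting. Includes a synthetic-data
    generator with planted interactor classes and intensity-dependent
    missingness so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
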