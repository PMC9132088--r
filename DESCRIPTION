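Package: aaplr
Title: Quantitative Analysis of Antigen-Antibody Proximity Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antigen-antibody proximity labeling (AAPL)
    oxidative proteomics. Computes site-level degrees of oxidation and the
    extent of protein oxidation (EPO) from peptide-level quantification
    tables, derives TopS-style AAPL interaction scores from oxidized spectral
    counts weighted by EPO, calls Level 1/Level 2 interactors, types
    interactors against STRING evidence (T1-T4), assembles annotated
    interaction networks, and classifies glycopeptide compositions for
    glycosylation-stratified interaction comparisons. Includes a synthetic
    data generator emulating proximity-dependent protein oxidation so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
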