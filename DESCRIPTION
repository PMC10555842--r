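Package: scdvp
Title: Single-Cell Deep Visual Proteomics Downstream Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis for single-cell Deep Visual Proteomics
    (scDVP) of zonated liver tissue: reference-channel ratio quantification
    of multiplexed-DIA precursor reports, MaxLFQ protein-group collapse,
    sample quality filtering and complete-protein median normalization,
    spatial zonation statistics along the portal-to-central axis (binning,
    moderated ANOVA, flatness testing, bin profiles, pseudo-neighbors),
    contour and image-patch feature extraction, k-means proteome classes
    with an image-feature random-forest classifier and probability-weighted
    spatial proteome prediction, plus a synthetic zonated-lobule generator
    that emulates the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    randomForest,
    xml2,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
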