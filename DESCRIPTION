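Package: discquant
Title: Cell-Type Quantification of Perinuclear Marker Intensity in Multiplex Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to rank a target protein's abundance across brain cell
    types from multichannel immunofluorescence images: DAPI nuclei counting
    (difference-of-Gaussians, triangle threshold, watershed), regional
    background-corrected intensity-per-cell scores with quartile levels,
    background-subtracted Manders colocalization in distance-banded
    sub-regions, per-cell perinuclear "disc" quantification (cell detection,
    nucleus expansion, pixel classification, diffuse-signal correction,
    upper-quartile normalization, exclusion rules), one-way and blocked
    two-way ANOVA with Tukey post hoc tests and assumption diagnostics, and
    cluster-level single-cell expression class summaries.  A synthetic-data
    module generates multichannel tissue scenes, control images, annotation
    masks and cluster-expression matrices with known ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
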