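Package: wearbench
Title: Simulation and Quantification of Erosive Tooth Wear from Sequential 3D Scans
Version: 0.1.0
Authors@R: person("Wearbench", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify erosive tooth wear between sequential 3D scans
    of a tooth crown. Implements two rigid-alignment strategies used in dental
    wear research (unconstrained best-fit iterative closest point on reference
    surfaces, and feature-initialised trimmed iterative closest point with a
    25 micrometre inlier band), wear outcome metrics measured perpendicular to
    the occlusal surface (volume change, maximum point loss, mean profile
    loss, positive-truncation secondary analysis), the accompanying
    nonparametric statistical layer (Wilcoxon signed-rank, Bonferroni
    correction, single-measures intraclass correlation, a-priori power
    analysis for a correlation), and a synthetic dental-scan generator that
    emulates laboratory profilometry and intraoral scanning with known
    ground-truth wear volumes and pose offsets, so that every stage of the
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
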