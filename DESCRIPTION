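Package: powdermetrics
Title: Characterization of Ultrafine Milled Biomass Powders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for powders produced by fine comminution of
    lignocellulosic feedstocks (e.g. pine bark, wheat straw) in ball mills.
    Computes particle size distribution statistics (d10/d50/d90, span,
    volume-specific surface area with a lower size cut), quantifies soft and
    hard agglomeration from ultrasonic-dispersion PSD triplets, performs
    population-balance style size-class shift accounting, derives particle
    shape morphometrics (elongation, convexity, Feret geometry) from
    silhouettes, computes powder rheology indices (Carr index, bed
    compressibility, Mohr-Coulomb cohesion), and ranks powders with a
    normalized multi-criteria radar-area score. A synthetic-data generator
    with known ground truth emulates the instrument exports so that the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
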