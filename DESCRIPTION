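Package: flyTurnover
Title: Fluorescent Protein Turnover Assays in Free-Moving Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring protein half-life in vivo from fluorescent
    reporter decay in adult Drosophila. Quantifies total fly fluorescence per
    video frame by threshold detection inside a region of interest, merges
    synchronized dual-camera streams, aggregates per-frame values into per-vial
    daily time courses, fits log-linear decay from the expression peak to the
    subsequent minimum to estimate half-life, and compares groups with ANCOVA
    on decay slopes, area-under-curve fold changes, t-tests, and two-factor
    ANOVA of half-life on age and sex. Includes a synthetic-experiment
    simulator (moving fluorescent flies on video, plate-reader decay series,
    stratified half-life tables) with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    tiff,
    yaml,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
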