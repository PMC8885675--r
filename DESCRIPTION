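Package: oolite
Title: Granulometric Provenance Analysis of Oolitic Limestone
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative provenance analysis of oolitic limestone from
    cross-section imagery and micro-CT volumes. Extracts per-ooid Feret
    diameters from grayscale cross-sections (thresholding, median-filter
    denoising, distance-transform watershed separation, border exclusion,
    shape-based selection), compares per-site grain-size distributions by
    the Hellinger distance between Silverman-bandwidth kernel density
    estimates of log diameters, embeds sites by principal coordinate
    analysis of the Hellinger distance matrix, and measures dense
    sub-spherical inclusions in 3D volumes via half-maximum-height
    thresholding and moment-tensor ellipsoid axes. Includes a seeded
    synthetic-oolite generator (grain-diameter mixtures, rendered
    cross-sections, rendered volumes) with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    Rcpp,
    yaml,
    jsonlite,
    tiff,
    png,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
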