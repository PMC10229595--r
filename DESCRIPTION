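Package: gigamosaic
Title: Distortion-Compensated Gigapixel Mosaicking and Virtual H&E
    Rendering for Nonlinear Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for assembling gigapixel whole-slide mosaics from
    tiled nonlinear-microscopy scans. Implements a radial field-of-view
    distortion model with grid-search parameter estimation from tile
    overlaps, resonant-scanner cosinusoidal resampling correction,
    stage-informed tile alignment with a sigma-scored coarse-to-fine
    search, virtual hematoxylin-and-eosin color remapping of two-channel
    (THG/TPEF) images via Beer-Lambert lookup tables, an uncompressed
    large-image bitmap container with embedded preview and region-of-
    interest reads, diagnostic-accuracy statistics, and a synthetic scan
    simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
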