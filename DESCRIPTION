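Package: dic4d
Title: 4D Reconstruction and Motion Analysis of Cell Aggregates in DIC Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs and motion-analyzes multicellular aggregates growing in
    transparent 3D gels from long-term time series of differential interference
    contrast (DIC) optical sections. Provides in-focus object detection per
    optical section via a local-complexity bitmap, stacking of detections into
    watertight faceted 3D models by adaptive facet-merging surface extraction,
    beta-spline smoothing of manually traced cell outlines, frame-to-frame
    tracking with coalescence detection and slash-coded lineage identifiers,
    field-edge entry/exit bookkeeping, and a 3D motility and contour parameter
    suite (centroid, volume, surface complexity, speed, percent original
    aggregate number). A synthetic phantom generator renders DIC-like 4D stacks
    of scripted aggregate scenes with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
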