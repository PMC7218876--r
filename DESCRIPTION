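Package: cloudspectra
Title: Multispectral Enrichment and Unsupervised Material Segmentation of Photogrammetric Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses calibrated multispectral imagery (green, red, red-edge,
    near-infrared) with photogrammetric RGB point clouds and segments the
    enriched cloud into natural-material clusters without a known cluster
    count.  Provides radiometric calibration of raw multispectral pixels to
    surface reflectance via a sunshine-sensor model and calibration panel,
    a polynomial fisheye projection of 3D points into image coordinates,
    surfel-based visibility testing with occlusion rejection, ICP rigid
    registration of point clouds, view-angle-weighted multi-view reflectance
    aggregation, NDVI computation, and divisive bisecting-k-means clustering
    with a diameter-based stopping rule.  A synthetic-scene generator renders
    physically consistent multispectral captures of labelled scenes so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RANN,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
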