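Package: phytocloud
Title: Chlorophyll and Leaf-Angle Monitoring from Colored 3D Plant Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-destructive plant monitoring from colored 3D point
    clouds reconstructed by structure-from-motion photogrammetry. Establishes
    metric scale and a gravity-aligned frame from a reference cube of known
    dimensions, estimates per-point chlorophyll content from the normalized
    Red value R/(R+G+B) via a linear calibration against spectrophotometric
    measurements (Porra equations), estimates per-point leaf inclination
    (zenith) and azimuthal angles by orthogonal least-squares plane fitting
    in cubic neighborhoods, and aggregates the fields into per-leaf
    histograms, per-region time series and between-day significance tests
    for water-stress monitoring. Includes a synthetic canopy generator with
    known ground truth for validation, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
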