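Package: BudQuant
Title: Quantitative Morphometry of Embryonic Mammary Rudiments from
    Serial Histological Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures early growth of embryonic skin-appendage rudiments
    (mouse mammary buds) from serial BrdU-immunostained histological
    sections. Provides compartment segmentation of sections into
    ectoderm, rudiment core/periphery/neck and mammary versus dermal
    mesenchyme from manual contour annotations; BrdU-incorporation
    quantification by colour thresholding; rudiment volumetry by
    Levenberg-Marquardt curve fitting of area-versus-depth profiles;
    arithmetic models for ectodermal cell influx and peripheral-cell
    hypertrophy; 3D stack reconstruction with non-reflective similarity
    registration, nucleus extraction and splitting, and iso-surface
    meshes; and a synthetic-histology phantom generator with full ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    minpack.lm,
    jsonlite,
    pracma,
    png,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
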