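Package: hsibruise
Title: Nondestructive Blueberry Bruise Detection from NIR Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting and quantifying blueberry bruising from
    near-infrared hyperspectral reflectance cubes (950-1650 nm): ENVI cube
    input/output, flat-field reflectance calibration, automatic berry
    segmentation with calyx-end exclusion, pixel-level support-vector
    classification of healthy versus bruised tissue, a per-fruit bruise ratio
    index, firmness from force/deformation curves and partial least squares
    firmness prediction from mean spectra, and the accompanying statistical
    comparison suite (MANOVA on spectra, Kruskal-Wallis with Dunn-type
    post-hoc letters, linear regression against human assessment, ANOVA on
    bruised-fruit counts). Includes a synthetic hyperspectral phantom
    generator with known ground truth so the full pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
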