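Package: fibrescreen
Title: High-Throughput Screening of Extracellular-Matrix Fiber Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis pipeline for high-content screens of
    extracellular-matrix (ECM) fiber alignment in cell-derived matrices.
    Computes per-pixel fiber orientation from confocal maximum-intensity
    projections via a structure tensor, summarises each field of view by the
    fraction of fiber orientations within 20 degrees of the histogram mode,
    applies a three-tier quality-control cascade (field of view, well,
    treatment), counts nuclei for a toxicity filter, and calls screening hits
    with robust Z-scores against negative controls composited across replicate
    plates.  Includes a synthetic plate simulator with known orientation
    anisotropy and planted compound effects so the whole pipeline is testable
    without microscope data, plus assay-credentialing statistics (Z'-factor,
    coefficient of variation) and fluorescent-labeling reagent calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
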