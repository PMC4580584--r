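Package: rootanat
Title: Automated Morphometric Analysis of Plant Root Cross-Section Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated analysis of stained root cross-section
    micrographs of cereal plants. Segments cell walls from an inhomogeneous
    background by local mean-difference thresholding, detects every enclosed
    cell, classifies cells into anatomical tissues (epidermis, cortex,
    endodermis, stele, metaxylem, and for maize protoxylem and aerenchyma)
    using rule-based morphology, and reports primary per-tissue statistics
    together with radial "cheesewheel" morphometrics. Includes a synthetic
    root cross-section generator with exact per-cell ground truth for
    validation, and a batch command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
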