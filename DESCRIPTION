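Package: proxsim
Title: Simulation and Protein-Complex Inference for Single-Cell
    Proximity Sequencing (Prox-seq) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A geometric simulator of single-cell proximity ligation assay
    (PLA) product counts, in which DNA-barcoded antibody probes are placed as
    random points on a spherical cell surface and ligated when closer than a
    ligation distance.  The package provides closed-form proximity-noise
    theory, four protein-complex inference procedures (an iterative
    expected-count subtraction, a weighted-least-squares regression on
    non-proximal "free oligo" counts, an ensemble of the two, and a per-cell
    one-sided Fisher's exact test), and a simulation-based benchmark that
    scores predictors against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
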