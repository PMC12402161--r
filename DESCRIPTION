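Package: CellSqueeze
Title: Quantitative Image Analysis for Microfluidic Constriction Cytometry
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the quantitative pipeline for measuring
    constriction-induced cell-state change in a microcapillary-mimicking
    device: deformation-index morphometrics across constriction channels and
    relaxation chambers, flatfield/darkfield illumination correction, minimum
    cross-entropy thresholding with seeded watershed and propagation-based
    single-cell segmentation, two-compartment (nuclear/cytoplasmic)
    immunofluorescence profiling with robust outlier filtering and
    Mann-Whitney/Benjamini-Hochberg group statistics, calcium fold-change
    extraction, endothelial permeability coefficient estimation, tumorsphere
    growth quantification, and threshold-based differential-expression
    classification. A seeded synthetic-microscopy generator provides all
    pipeline inputs with known ground truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    uwot,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Software, Visualization
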