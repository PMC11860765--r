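Package: censtab
Title: Quantification of Chromosome Stability Assays from Flow and Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators and simulators for chromosome-stability assays built
    around human artificial chromosomes (HACs) and centromere imaging. Computes
    the per-division rate of HAC loss from GFP-positive fractions, with the
    division index fitted from dye-dilution flow cytometry as a constrained
    halving-peak mixture; quantifies FISH and immunofluorescence foci with the
    per-cell median-focus procedure (perimeter-median background subtraction,
    anchored two-channel quantification, control normalization); runs an
    object-based 3D colocalization pipeline (Otsu nucleus segmentation,
    nucleus individualization and QC, seeded spot segmentation, focus-volume
    overlap with a minimum-overlap filter); and counts colonies with a
    circularity filter. Synthetic-data generators with full ground truth make
    every stage testable without raw microscopy or flow files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
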