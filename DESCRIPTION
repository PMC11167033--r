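Package: cafcontact
Title: Quantitative Time-Lapse and Immunofluorescence Analysis of
    Fibroblast-T Cell Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative microscopy of
    cancer-associated fibroblast (CAF) and regulatory T cell (Treg)
    interactions. Detects spot-like motile cells with a Laplacian-of-Gaussian
    filter, links detections into trajectories with gap closing, segments the
    textured fibroblast-occupied area by local contrast, measures per-frame
    cell-to-stroma contact and contact-episode durations, classifies
    immunofluorescence fields into marker-rich and marker-poor regions with
    per-region cell densities, and counts fluorescent puncta per cell for
    autophagic-flux readouts. Includes seeded synthetic-image generators with
    full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
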