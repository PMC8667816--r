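Package: mitoquant
Title: Quantitative Analysis of Mitotic Inhibitor Screens and Single-Molecule
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the quantitative assays used to characterise
    small-molecule inhibitors of the kinetochore-microtubule interface:
    consensus rescoring of multi-function docking results with Z-score voting,
    fluorescence-anisotropy binding isotherms with ligand depletion,
    single-molecule TIRF residence-time (off-rate) and mean-squared-displacement
    (diffusion) analysis, kinetochore oscillation and inter-kinetochore distance
    metrics, and cell-population summaries (mitotic/death indices, cell fate
    tables, four-parameter logistic EC50 fits, Bliss combination analysis).
    Seeded synthetic-data generators emulate each assay so that every estimator
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
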