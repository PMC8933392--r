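Package: ihcgate
Title: Quantitative DAB Immunohistochemistry Scoring and Mixture-Model
    Gating of Cyclic Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Semi-automated percent-positive scoring of DAB
    immunohistochemistry with hematoxylin counterstain: Beer-Lambert
    optical-density conversion, H-DAB color deconvolution, nucleus
    detection with a uniform hematoxylin threshold, and DAB positivity
    calling in nucleus or cytoplasm. The DAB threshold is calibrated
    against manual observer counts by Bland-Altman agreement analysis,
    and sections are classified at a 30 percent positivity cutoff.
    Companion tools normalize multi-sample single-cell fluorescence
    intensity tables, fit two-component Gaussian mixtures per marker
    with the positive gate at the peak of the positive component, and
    apply rule-based single-cell phenotyping. A synthetic-data module
    generates stained tissue images, intensity tables, and observer
    counts with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
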