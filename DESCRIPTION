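Package: mgstratify
Title: Cell-Based Stratification of Anti-AChR Myasthenia Gravis Patients by
    Complement-Dependent Receptor Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies acetylcholine receptor (AChR) expression, patient
    autoantibody binding and membrane attack complex (MAC) deposition from
    multi-channel fluorescence images of AChR/Rapsyn-transfected cell
    monolayers, and turns the per-well readouts into an ordinal, four-way
    patient categorization reflecting complement-dependent AChR loss and its
    blockade by terminal-pathway (anti-C7) inhibition. Includes per-cell
    nuclei/cytoplasm segmentation, Laplacian-of-Gaussian spot quantification
    with percent-positive thresholding, per-plate fold-change normalization
    against a normal-human-serum control, printed-band ordinal classifiers,
    four-parameter logistic dose-response fitting (hemolysis EC50/IC50,
    standard-curve back-interpolation with dilution factors and optional
    1/y^2 weighting), and a seeded synthetic-imaging and cohort generator so
    every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
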