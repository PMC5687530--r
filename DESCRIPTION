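Package: lungqct
Title: Multiscale Quantitative-CT Lung Phenotyping with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiscale quantitative computed tomography (QCT)
    phenotyping of obstructive lung disease. Computes airway morphometry
    (circularity, hydraulic diameter, normalised wall thickness),
    fraction-threshold densitometry (emphysema percent, functional
    small-airways disease percent with parametric-response-map style
    subtraction, lobar tissue fraction) and registration-derived lung
    mechanics (Jacobian determinant, anisotropic deformation index,
    fractional lobar air-volume change), and compares healthy, asthma and
    COPD cohorts with rank-based tests under Benjamini-Hochberg false
    discovery rate control. A seeded synthetic phantom and cohort generator
    provides paired inspiration/expiration volumes with exact ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
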