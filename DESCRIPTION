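Package: ramanTreg
Title: Label-Free Detection of Regulatory T Cells from Single-Cell Raman
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying regulatory T cells (Tregs) among
    conventional CD4+ T cells (Tconv) from single-cell Raman spectra.
    Implements the full analysis chain: spectral preprocessing (cosmic-ray
    removal by median filtering, iterative cubic-spline baseline
    correction, wavenumber calibration against a reference spectrum,
    silent-region excision, PCA-based outlier filtering), L1-regularized
    logistic classification with separation-vector band annotation,
    confident-learning pruning of cells mislabeled by imperfect
    cell-sorting purity, mixture scoring of unlabeled validation pools,
    and donor-holdout evaluation. A synthetic-cohort generator with known
    phenotype band effects, acquisition artifacts, donor/batch structure
    and sort-impurity label corruption makes every stage testable without
    access to measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
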