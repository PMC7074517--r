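Package: plsfuse
Title: Low-Level Data Fusion, PLS-DA and SIMCA Class Modeling for
    Multi-Platform Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control biomarker discovery across multiple
    measurement platforms. Implements low-level (measurement-level) data
    fusion with per-variable autoscaling and per-block Frobenius-norm
    normalization, partial least squares discriminant analysis (NIPALS
    PLS1 on a binary dummy response), repeated double cross-validation
    with number-of-misclassifications, AUROC and discriminant-Q2 figures
    of merit, permutation testing, biomarker ranking by variable
    importance in projection and rank products of regression coefficients
    across resampling segments, and one-class SIMCA modeling with reduced
    Hotelling T2 / Q-residual distances. Includes a seeded log-normal
    cohort simulator for a three-platform serum biomarker panel so the
    whole pipeline can be exercised without access to raw patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
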