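Package: cfmeth
Title: Plasma Cell-Free DNA Methylation Marker Panels for Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating CpG-island hypermethylation
    biomarker panels from semi-targeted cell-free DNA methylation assays that
    report methylated alleles per million mapped molecules (MEPM). Implements
    quality control and cohort partitioning, differential methylation testing
    (exact Mann-Whitney with tie handling, Benjamini-Hochberg correction),
    four-criteria tumor-marker selection, a positivity-counting classifier
    with Monte Carlo cross-validated panel sizing by Brier score and
    normal-plasma cutoff calibration, a LASSO-logistic methylation score with
    waterfall classification and stage flags, consensus-clustering CIMP
    subtyping, and a multi-panel tumor-origin typing algorithm. Ships a
    ground-truthed synthetic cohort generator emulating paired tissue and
    plasma cohorts for four gastrointestinal cancer types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
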