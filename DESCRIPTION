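Package: immunomethyl
Title: Methylation-Derived Immune Cell Ratios for Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Immunomethylomic analysis of blood DNA methylation: selection of
    leukocyte-subtype-specific CpG markers from a reference methylome,
    quantification of immune-cell-ratio proxies and methylation-derived
    neutrophil-to-lymphocyte ratios (mdNLR) from beta values, reference-based
    deconvolution of leukocyte proportions by constrained projection, and the
    matched case-control inference toolkit (1:1 conditional logistic
    regression, AUC with DeLong intervals, Holm correction, backward
    selection, optimism-corrected bootstrap validation, and rank-based
    tests). Includes a calibrated synthetic-cohort generator used as the
    test substrate for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
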