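Package: respiromics
Title: Respiratory Muscle CT Radiomics and Simplified Slice-Sampling Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of respiratory-muscle sarcopenia
    from unenhanced chest CT. Provides a calibrated synthetic-cohort generator
    (CT-like muscle volumes with aligned binary masks), slice-stack construction
    with pixel-count and z-score exclusion rules, an IBSI-style radiomic feature
    extractor (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM), per-slice
    Jensen-Shannon density profiling with data-driven landmark selection,
    landmark-anchored 1/3/5/7-slice sampling protocols with offset robustness
    analysis, MAE/MAPE deviation evaluation against whole-muscle references with
    a normality-routed statistical battery, and a sarcopenia biomarker-selection
    workflow (feature cleaning, penalized logistic selection, backward
    refinement, and cluster odds ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
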