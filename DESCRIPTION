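Package: ncrtfusion
Title: Attention-Fusion SVM Modelling of Neoadjuvant Chemoradiotherapy
    Response in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting response to neoadjuvant
    chemoradiotherapy (NCRT) in locally advanced rectal cancer from baseline
    MRI-derived clinical markers. Provides a seeded synthetic-cohort
    generator calibrated to published pre/post treatment summary statistics,
    paired pre/post screening tests (paired t, McNemar, Stuart-Maxwell),
    z-score standardization, an attention-based feature-fusion layer with
    learnable query/key/value parameters, a soft-margin RBF support vector
    machine, leave-one-out cross-validation with accuracy/AUC/sensitivity/
    specificity reporting, exhaustive feature-subset ablation over all 127
    combinations of the seven model features, and top-K per-feature
    proportion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
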