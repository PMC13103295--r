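Package: cpmtools
Title: Connectome-Based Predictive Modeling of Behavioral Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of a behavioral
    severity score from functional connectivity: Fisher-z edge features,
    covariate-adjusted edge selection into positive and negative networks,
    network-strength linear models, leave-one-out and k-fold
    cross-validation, permutation-test significance, fixed-model external
    validation, and canonical-network summaries of selected edges. Includes
    a synthetic connectome generator with planted predictive edges and
    covariate confounds so the entire pipeline is testable end to end with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
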