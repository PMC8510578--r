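Package: larvalearn
Title: Individual-Animal Learning Analysis for Y-Maze Choice Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of repeated binary odor choices made by
    individual Drosophila larvae in a Y-maze conditioning assay.  Provides
    decision-weighted preference indices, hierarchical and animal-only
    bootstrap inference on nested choice data, exact tests on pooled
    pre/post decision counts, and maximum-likelihood competition between
    graded, quantized, and all-or-none (exponential-fraction) learning
    models with AIC/BIC selection and profile-likelihood intervals on the
    trained fraction.  Includes a generative simulator for serially
    correlated two-alternative choice data with per-cycle all-or-none
    state switching, used for parameter-recovery and model-selection
    calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
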