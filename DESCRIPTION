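Package: neurodyn
Title: Multiscale Nonlinear Dynamics and Supervised Tensor Biomarkers for EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multiscale nonlinear dynamical invariants from
    multichannel neurophysiological recordings (recurrence quantification,
    recurrence networks, entropies, fractal and chaos measures, band power),
    organizes them as a fourth-order subjects x sensors x bands x measures
    feature tensor, extracts latent factors by supervised canonical polyadic
    decomposition, and maps latent factors to a behavioral target with
    cross-validated regression. Includes synthetic dynamical systems and an
    age-modulated synthetic EEG cohort generator so the full pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
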