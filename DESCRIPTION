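Package: coropod
Title: Reduced-Order Reconstruction of Pressure and Wall Shear Stress in
    Coronary-Artery-Like Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A physics-based machine-learning pipeline for rapid
    reconstruction of steady pressure and wall-shear-stress fields in
    coronary-artery-like vessels. Generates synthetic vessel phantoms by
    randomised two-sinusoid radius perturbation of reference shapes,
    solves steady generalized-Newtonian (Carreau-Yasuda) tube flow with a
    pluggable quasi-1D surrogate solver, extracts common-base proper
    orthogonal decomposition (cPOD) modes and principal coefficients by
    the snapshot SVD method, embeds mesh shapes in two dimensions with
    t-SNE, learns the embedding-to-coefficient map with a chained
    random-forest regressor, and reconstructs and scores fields with
    range-normalised NMAE/NRMSE error metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
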