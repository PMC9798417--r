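Package: metafinger
Title: Ambient Mass-Spectrometry Metabolic Fingerprinting for Diagnostic Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for ambient-ionization mass-spectrometry
    metabolic fingerprinting of clinical cohorts: scan averaging and
    fixed-tolerance mass binning into a samples-by-features peak matrix,
    total-ion-current normalization with log autoscaling and QC-based
    stability reporting, PLS-DA with variable-importance-in-projection (VIP)
    scores, a stepwise marker-selection cascade (VIP, Benjamini-Hochberg FDR,
    fold change), formula-based adduct annotation with ppm matching and
    isotope-ratio plausibility checks, sparse (lasso) diagnostic panel
    fitting with cross-validation and ROC evaluation, tissue-to-serum marker
    tracking with single-point concentration estimates, and per-ion image
    reconstruction from raster line scans. Includes a synthetic cohort and
    spectrum generator so the full pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mzR
Config/testthat/edition: 3
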