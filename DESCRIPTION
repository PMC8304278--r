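Package: polyphos
Title: Two-Tier Screening and Confirmation of (Poly)phosphate Additives in Food
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting undeclared (poly)phosphate additive treatment
    (E450/E451/E452) in food of animal origin from ion-chromatography data.
    Implements a conductometric-channel screening tier based on relative
    retention times against the orthophosphate anchor peak, and a
    high-resolution mass-spectrometry confirmation tier based on exact
    deprotonated-anion masses, data-independent-acquisition fragment
    co-elution and a long-chain polyphosphate "fingerprint". Includes
    chromatographic peak detection with robust baseline and signal-to-noise
    estimation, calibration with LOD/LOQ, censored quantification,
    a rule-based per-sample treatment verdict, and a seeded synthetic
    chromatogram/scan-set generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
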