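Package: specmix
Title: Multivariate Calibration for Overlapping UV-Vis Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric quantification of spectrally overlapping analytes
    from UV-Vis absorption spectra. Implements classical least squares (CLS),
    principal component regression (PCR) and partial least squares (PLS2,
    NIPALS) calibration with a common fit/predict contract, the five-level
    two-factor multilevel calibration design used to lay out binary drug
    mixtures, leave-one-out cross-validation with RMSECV-based latent
    variable selection, analytical figures of merit (recovery statistics,
    LOD/LOQ, accuracy and precision protocols, standard addition, t/F method
    comparison) and analytical eco-scale greenness scoring. A seeded
    Beer-Lambert spectra simulator with Gaussian band shapes, instrument
    noise and an optional plasma-like interferent background makes every
    stage testable without instrument data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
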