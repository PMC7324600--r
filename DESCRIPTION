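Package: phonovibe
Title: Vocal-Fold Vibration Parameters from Glottal-Area Signals and
    Boosted-Stump Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates vocal-fold oscillations as recorded by laryngeal
    high-speed videoendoscopy, extracts the standard glottal-area-waveform
    (GAW) and Phonovibrogram (PVG) vibration parameters (jitter, shimmer,
    quotients, harmonics-to-noise ratio, left-right symmetry, contour
    angles), prunes redundant parameters by Pearson correlation, and ranks
    the remainder with from-scratch boosted decision stumps (AdaBoost,
    LogitBoost, RUSBoost) under repeated stratified cross-validation to find
    a small parameter subset separating healthy from functionally dysphonic
    voices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    xgboost,
    withr
Config/testthat/edition: 3
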