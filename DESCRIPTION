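Package: sicdscreen
Title: Prolonged S-ICD Eligibility Screening from Holter ECG via Phase
    Space Reconstruction Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prolonged (24-hour) subcutaneous implantable
    cardioverter-defibrillator (S-ICD) eligibility screening from
    three-channel Holter ECG recordings used as surrogates of the S-ICD
    primary, alternate and secondary sensing vectors.  Recordings are
    split into 10-second segments, conditioned (baseline-drift removal,
    adaptive 50 Hz notch, low-pass), converted to 32x32 phase space
    reconstruction (PSR) images by time-delay embedding, and the T:R
    amplitude ratio of each segment is estimated either by a rule-based
    fiducial-peak detector or by a compact convolutional regressor
    trained on the PSR images with 10-fold cross-validation.  Screening
    statistics (per-vector failure probability at the 1:3 cut-off,
    mean/median/SD of T:R, Welch group comparisons) and T:R variation
    plots are produced.  A synthetic Holter generator with programmable
    T:R dynamics provides fully ground-truthed data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ggplot2,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
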