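Package: driverattn
Title: Multimodal Pre-Stimulus Physiology and Reaction-Time Modeling for
    Automation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying driver attention to automation failures in
    semiautonomous (SAE Level 2) driving from multimodal physiology. The
    package extracts pre-stimulus features time-locked to automation-failure
    signals -- heart-rate metrics (meanRR, RMSSD) from wavelet-based (MODWT)
    R-peak detection on ECG, parietal alpha-band power from Hamming-windowed
    spectra of 1-s pre-stimulus EEG epochs, and log gaze dispersion from
    confidence-filtered eye-tracking -- scores detection behavior with the
    non-parametric A sensitivity statistic, and models reaction time to
    failure signals with interactive linear mixed-effects models compared by
    likelihood-ratio tests, with Nakagawa marginal and conditional R-squared.
    A synthetic multimodal session generator with known ground truth supports
    end-to-end validation and parameter-recovery studies.
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
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
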