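Package: meaflow
Title: Multi-Electrode Array Spike-Train Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of in vitro multi-electrode array (MEA)
    recordings of cultured neuronal networks: extracellular spike detection by
    robust noise-scaled thresholding, removal of device-wide heater artifacts,
    channel quality control, per-channel burst detection with a five-parameter
    maximum-interval definition, firing and bursting feature extraction with
    per-device aggregation, time-resolved SPIKE-distance synchrony normalized
    against a Monte-Carlo null of count-matched uniform random spike trains,
    drug-challenge fold-change comparison, and ANOVA/Tukey group statistics.
    Includes a synthetic MEA generator (Poisson background firing, coordinated
    network bursts, biphasic spike waveforms in Gaussian noise, device-wide
    heater artifacts) that provides ground truth for validating every stage.
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
    withr,
    yaml
Suggests:
    optparse,
    rhdf5,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
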