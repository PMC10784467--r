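Package: gaitdx
Title: Gait-Based Disease Classification from Body Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing gait-affecting disease (peripheral artery
    disease as the case study) from body acceleration. Derives acceleration
    from reflective-marker trajectories by double differencing and Butterworth
    low-pass filtering, detects initial and final contacts with a Gaussian
    continuous-wavelet procedure, extracts sixteen temporal gait features
    (four base means plus magnitude-of-variability, step-variability and
    step-asymmetry for each), and trains and evaluates classifiers across
    marker-trained / wearable-tested modality paths. A synthetic walking-data
    simulator with ground-truth gait events makes every pipeline stage
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
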