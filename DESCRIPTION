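Package: reflexkit
Title: Quantification of Airway-Closure Reflexes from Respiratory, Calcium
    and Nerve Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify a vagally mediated airway-closure reflex from
    physiological recordings: segmentation of respiratory pressure and flow
    traces into breaths, detection of gasps and sighs by amplitude-ratio
    rules, eupneic filtering and body-weight-normalized plethysmography
    summaries, stimulus-aligned reflex metrics (gasp frequency, latency,
    baseline normalization, Hering-Breuer rate suppression), ratiometric
    GCaMP/tdTomato delta-F/F0 analysis of vagal ganglion imaging with
    responsiveness calling and selectivity classification, and rectified
    leaky integration of multiunit nerve and EMG signals with
    serotonin-referenced response normalization. A synthetic-data module
    generates traces with known ground truth so every stage is testable
    without raw recordings.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
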