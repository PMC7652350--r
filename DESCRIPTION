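Package: sptlearn
Title: Serial Prediction Task ERP and Sequence-Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial prediction task (SPT) experiments that
    combine event-related potentials (ERPs) with behavioural sequence
    discrimination and visuomotor learning, as used to study internal forward
    modelling in children with Developmental Coordination Disorder. Provides a
    synthetic-data generator with known ground truth (P3-like evoked component,
    1/f plus white noise, Bernoulli accuracy, power-law reaction-time learning),
    an EEG preprocessing chain (band-pass FIR filtering, epoching, baseline
    correction, amplitude-threshold artifact rejection, low-trial participant
    exclusion, correct-trial averaging), a paired cluster-based temporal
    permutation test, percent-area latency estimation with leave-one-out
    jackknife inference and the F/(N-1)^2 adjustment, and behavioural accuracy
    and log-RT learning-slope analyses, tied together by a reproducible
    pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
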