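Package: spectralrsa
Title: Time-Resolved Spectral Pattern Similarity Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Representational similarity analysis of time-frequency-resolved
    EEG power. Computes within-item, within-category and between-category
    time-time correlation matrices (Fisher-z transformed) from single-trial
    spectral power after log transformation and 1/f background-spectrum
    removal, runs three-level cluster-based sign-flip permutation statistics
    for neural item specificity over channel x time x time volumes, compares
    item specificity between subject groups, and correlates it with memory
    performance. Includes a synthetic-data generator with planted
    representational structure for parameter-recovery and error-control
    studies, FieldTrip MAT import, ggplot2 figures and a step-wise command
    line pipeline.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
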