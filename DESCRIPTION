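Package: sigspace
Title: Modular Node-Chain Processing and Classification of Windowed
    Multichannel Time Series
Version: 0.1.0
Authors@R:
    person("sigspace", "maintainers", email = "sigspace@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for automated, parallel signal
    processing and supervised classification of windowed multichannel
    time series such as event-related potentials recorded with EEG.
    Continuous recordings are segmented into labelled epochs, pushed
    through modular trainable node chains (spatial filters such as
    xDAWN, CSP and PCA, feature generation, normalization, linear
    classification, stratified splitting and grid-search
    cross-validation), and benchmarked over YAML-specified parameter
    grids with constraints and seeded repetitions.  Independent
    processes run on serial or multicore back-ends under a
    result-equivalence contract and are consolidated into a single
    results table.  A synthetic oddball-paradigm generator with a
    planted spatial pattern makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
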