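Package: ozimpute
Title: Graph-Based Imputation of Missing Air-Quality Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of gaps in hourly pollutant concentration panels from
    irregular monitoring networks. Provides statistical and machine-learning
    base imputers (spatiotemporal and spatial means, linear interpolation,
    nearest-neighbor hybrid, gridded reference fields, random forests), a
    spatiotemporal station graph with distance-decay edge weights, and a
    regression adaptation of the correct-and-smooth residual/label propagation
    algorithm that postprocesses any base imputer using observations at
    neighboring stations. Includes gap detection and classification,
    gap-structure-preserving train/validation/test masking, per-gap-class
    evaluation metrics, a synthetic network simulator for end-to-end testing
    without external data, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    class,
    stats,
    utils,
    yaml,
    methods
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
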