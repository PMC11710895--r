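Package: dynconn
Title: Dynamic Brain-Network Tensors, HOSVD Reduction, and Group Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds sliding-window dynamic functional-connectivity tensors
    from region-of-interest fMRI time series, reduces them with a
    higher-order singular value decomposition to low-rank network
    components, and predicts behavioral-change groups (sitting time and
    daily step count, split at the cohort median) with a linear support
    vector machine under repeated balanced subsampling and a
    label-permutation null. Includes a seeded synthetic-cohort generator
    with band-limited signals and planted group-dependent dynamic
    connectivity, so the whole pipeline is testable without access to
    scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
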