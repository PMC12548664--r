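Package: dfcnet
Title: Temporal Brain Networks, Narrative Classification, and Shapley
    Subnetwork Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dynamic functional connectivity (temporal brain
    network) tensors from region-of-interest BOLD time series via
    nuisance regression, zero-phase band-pass filtering, sliding-window
    Pearson correlation and per-edge Z-normalization; classifies
    narrative modality and content with a time-axis convolutional model
    (single convolutional layer spanning all region pairs, global
    max-pooling over time, multilayer perceptron head); attributes
    classification accuracy to brain subnetworks with exact and
    permutation-sampled Shapley values over coalition-masked inputs; and
    provides seeded permutation and static-connectivity controls. A
    covariance block-model simulator generates seeded synthetic datasets
    with planted, subnetwork-localized class effects so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
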