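Package: micsp
Title: Motor-Imagery EEG Decoding with CSP, Sub-Band Features, and Sparse
    Log-Penalty Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding toolkit for two-class motor-imagery
    electroencephalography (EEG). Implements common spatial pattern (CSP)
    spatial filtering, three CSP-based feature extractors (discrete-wavelet
    sub-band energy and standard-deviation features, wavelet-packet features,
    and filter-bank log-variance features), sparse feature selection by
    proximal gradient descent under either an L1 (LASSO) or a non-convex
    logarithmic penalty solved by iterative log thresholding, and a
    threshold-grid ensemble of Fisher linear discriminant classifiers. Ships
    a synthetic EEG generator with event-related desynchronization structure
    so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
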