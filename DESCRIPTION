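Package: BCInav
Title: Motor-Imagery BCI Decoding and Shared-Control Navigation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hardware-free implementation of a motor-imagery
    brain-computer interface (BCI) for virtual street navigation. Provides a
    synthetic EEG generator with event-related desynchronization (ERD) of mu
    and beta rhythms, blink and artifact transients; an epoch data model with
    mastoid re-referencing, causal Butterworth filtering and amplitude-threshold
    artifact/blink detectors; a 20-band filter-bank common spatial pattern
    (FBCSP) front end; sliding-window statistical features; a bidirectional
    LSTM sequence classifier with a deterministic logistic baseline; the
    low-/middle-level navigation state machine with no-error-control, double
    confirmation and blink-based error-correction rotation strategies; and a
    closed-loop simulator with an abstract user model, analytic expectations
    for imagination counts, and rotation-error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
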