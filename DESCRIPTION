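Package: micnet
Title: Motor-Imagery EEG Analysis: ERD, Sub-Band CSP Classification and
    Transfer-Entropy Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for motor-imagery (MI)
    electroencephalography studies with three task conditions and two
    imagined hands. Generates synthetic EEG sessions with planted
    ground truth (contralateral alpha-band event-related
    desynchronization and condition-specific directed couplings),
    performs zero-phase FIR band-pass filtering, decimation and
    epoching, quantifies ERD/ERS as percentage band-power change from a
    pre-stimulus baseline, classifies left- versus right-hand imagery
    with sub-band common spatial patterns and Fisher linear
    discriminant analysis under repeated stratified cross-validation,
    estimates directed effective connectivity with a
    Kraskov-style k-nearest-neighbour transfer-entropy estimator over
    delay embeddings (Cao dimension selection, autocorrelation-decay
    delay selection), and contrasts relative transfer entropy between
    conditions across subjects with exact Wilcoxon signed-rank tests
    and Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
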