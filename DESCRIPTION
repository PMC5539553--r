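Package: fdbci
Title: Fractal-Dimension Features for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fractal-dimension feature extraction and channel selection for
    two-class motor-imagery brain-computer interfaces. Implements the
    Grassberger-Procaccia correlation dimension with saturation-based
    embedding selection (GPFD) and the Higuchi fractal dimension (HFD),
    together with band-power, autoregressive and common-spatial-pattern
    baseline features, Fisher-criterion channel ranking, and a
    leave-one-out cross-validated K-NN/LDA evaluation pipeline. Includes a
    synthetic-session generator (fractional Brownian motion backbones with
    planted class-dependent complexity) and reference signals of known
    fractal dimension for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    deSolve,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
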