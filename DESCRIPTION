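Package: hyfcnet
Title: Hybrid High-Order Functional Connectivity Networks from rs-fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs low-order, high-order and associated high-order
    functional connectivity (FC) networks from region-averaged resting-state
    fMRI time series, both statically and with a sliding window. Dynamic FC
    edge series are converted to frequency-power spectral networks by FFT,
    summarised per node with the weighted local clustering coefficient,
    reduced by PCA and LASSO, and classified with a multi-kernel linear SVM
    under nested leave-one-out cross-validation. Includes a synthetic cohort
    generator with planted time-varying coupling differences, group
    separability maps (squared point-biserial correlation), and broom-style
    tidiers and ggplot2 autoplot methods for the fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
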