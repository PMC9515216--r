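Package: ardaceph
Title: Ageing-Related Dynamic Attention Analysis for Cephalometric Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies where a convolutional age regressor looks on
    grayscale lateral-cephalometric-style radiographs and how that
    attention shifts with age. Trains a small convolutional network
    with L1 loss, derives per-subject ageing salience maps by Grad-CAM,
    averages them into per-age ageing-related dynamic attention (ARDA)
    maps, thresholds ageing-significant regions at percentile levels,
    quantifies salience per labeled anatomical instance, extracts the
    three attention-concentrated crops (teeth, craniofacial, cervical
    spine), and provides attention-constrained training with a two-pass
    retest inference rule. A seedable synthetic ageing-phantom generator
    with known per-instance change rates makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
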