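Package: bcenet
Title: Gated Adversarial Estimation and Hierarchical Graph Classification
    of Directed Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed (effective) connectivity among brain regions
    from multivariate ROI time series with a gated generative-adversarial
    network: one generative module per region predicts that region's signal
    from all others through a learnable causal gate, a shared discriminator
    scores one-to-one substituted synthetic samples, and the trained gate
    magnitudes are read out as a weighted directed connectome. A hierarchical
    graph neural network (graph convolution, TopK pooling, concatenated L1
    readouts) classifies the resulting brain networks. Includes Pearson
    correlation and bivariate Granger causality reference estimators, a
    nonlinear vector-autoregressive simulator with known ground-truth directed
    graphs, classification and structure-recovery metrics with stratified
    k-fold cross-validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    lmtest (>= 0.9),
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
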