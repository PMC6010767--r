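Package: omifa
Title: Sparse Bayesian Factor Analysis for Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised integration of multiple omics data matrices measured on
    shared samples. Fits a sparse Bayesian group factor analysis model in which a
    common set of latent factors explains variation across data modalities (views),
    with a two-level sparsity prior on the loadings: an automatic relevance
    determination (ARD) precision per factor and view, and a spike-and-slab prior
    for feature-wise sparsity. Inference is by mean-field variational Bayes with
    quadratic likelihood bounds for Bernoulli and Poisson views, so binary and
    count assays can be combined with continuous ones and arbitrary missing values
    (including whole missing assays) are handled natively. Includes factor pruning
    by explained variance, multi-restart model selection by the evidence lower
    bound, variance decomposition, feature-set enrichment on loadings, imputation
    with benchmark baselines, and a simulator drawing data sets from the
    generative model with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
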