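Package: noveltytagm
Title: Novelty Detection for Spatial Proteomics with T-Augmented Gaussian Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-supervised Bayesian analysis of quantitative spatial
    proteomics profiles. Fits a T-augmented Gaussian mixture model with
    additional overfitted "novelty" components, so that proteins are
    simultaneously assigned to known sub-cellular niches, flagged as
    outliers via a heavy-tailed multivariate Student-t component, or
    collected into newly discovered phenotypes. Inference uses a collapsed
    Gibbs sampler under conjugate Normal-Inverse-Wishart priors; posterior
    output is summarised through the posterior similarity matrix, maxPEAR
    consensus clustering, per-protein discovery and outlier probabilities,
    and putative-phenotype extraction. Includes a synthetic-data generator
    emulating the model's generative process, ggplot2 visualisations, and a
    thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
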