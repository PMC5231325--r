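Package: overmix
Title: Overfitted Bayesian Mixture Models for Selecting the Number of
    Latent Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing the number of latent classes in finite
    mixture models by deliberately overfitting: a Gibbs sampler for
    univariate Gaussian mixtures and for latent-class (growth) linear
    mixed-effects models is run with more components than the data are
    believed to contain, under a sparse symmetric Dirichlet prior on the
    mixing proportions, and the number of classes is estimated as the
    posterior mode of the per-iteration count of non-empty components.
    Competing criteria are provided for comparison: the mixture-adapted
    deviance information criteria DIC3 and DIC4 computed from the same
    MCMC output, and BIC computed from maximum-likelihood fits obtained
    by EM. Includes generators for the benchmark simulation scenarios
    (well- to poorly-separated Gaussian mixtures, unequal class
    proportions, outlier contamination, and random-intercept/slope
    growth mixtures) and a factorial simulation harness that tabulates
    success rates across priors, Dirichlet hyperparameters and
    empty-class cut-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
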