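Package: newtmix
Title: Bayesian N-Mixture Models for Newt Trap-Count Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Binomial-Poisson N-mixture models for estimating
    amphibian abundance from repeated trap counts under imperfect detection.
    Implements a marginalized likelihood with logit-linear detection,
    log-linear abundance and a site-level random effect, an adaptive
    Metropolis-within-Gibbs sampler, WAIC-based staged model selection over
    multi-scale landscape covariates, posterior summary tables with
    credible intervals and the f-statistic, and abundance response curves.
    Includes a synthetic-data generator that emulates a 32-site, two-survey
    funnel-trap study design so the whole workflow is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
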