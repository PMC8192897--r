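Package: mergm
Title: Multilevel Exponential Random Graph Models for School Friendship
    and Online Group Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits multilevel exponential random graph models (MERGMs) to
    directed school friendship networks with fixed bipartite affiliations
    to online groups, as used in process evaluations of peer-led health
    interventions.  Provides the full catalogue of structural,
    actor-relation and cross-level effect statistics with incremental
    change statistics, Metropolis-Hastings simulation on the constrained
    tie space (structural zeros for non-respondent senders, maximum
    out-degree conditioning), three-phase Robbins-Monro stochastic
    approximation maximum-likelihood estimation with convergence t-ratios
    and standard errors, simulation-based goodness-of-fit, a synthetic
    school-network generator emulating peer-led intervention study
    conditions, and per-school reporting with effects tagged to
    process-evaluation components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
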