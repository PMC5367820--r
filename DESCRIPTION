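Package: msceid
Title: Multistage Clonal Expansion Models and Practical Identifiability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hazard functions for the two-, three-, and four-stage clonal
    expansion (MSCE) models of carcinogenesis, Poisson maximum-likelihood
    fitting of age-specific cancer incidence data, and a practical
    identifiability toolkit: profile likelihoods, likelihood-based
    confidence intervals, subset-profiling dependency scans, and
    reparameterizations of the three- and four-stage hazards in terms of
    their practically identifiable parameter combinations. Includes a
    synthetic incidence generator emulating registry-scale data and an
    exact stochastic (Gillespie) branching-process oracle for validating
    the closed-form hazards.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
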