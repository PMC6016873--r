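Package: decidlab
Title: Compositional Cytometry and Decidualization Response Analysis for
    Menstrual Effluent Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis toolkit for case-control studies of
    menstrual effluent. Implements parent-gate normalization of flow
    cytometry cell populations with random-intercept linear mixed models
    (REML) for group association, a Bayesian hierarchical model of
    log-transformed IGFBP-1 decidualization time courses fitted by a
    conjugate Gibbs sampler with posterior tail probabilities for the
    case/control effect and posterior-predictive generated quantities,
    and comparative Ct (delta-delta-Ct) relative quantification of qPCR
    data with an exact Mann-Whitney test. A synthetic-data generator
    reproduces the statistical structure of such studies (log-normal
    protein responses with subject and residual variance components,
    Dirichlet-multinomial gate compositions with a case-specific uNK
    shift) so that every stage of the pipeline is testable without
    access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    coda,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
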