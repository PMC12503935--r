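Package: cueload
Title: Selection Against Deleterious Alleles and Genetic Load Under
    Variable Environmental Cues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference pipeline for estimating selection
    against recessive deleterious alleles from inbred/outbred viability and
    maternal-care behaviour under different environmental-cue regimes.
    Provides a synthetic-data generator for grouped behavioural trials,
    egg-placement counts, bean-level larval survival and female fecundity;
    maximum-likelihood fitting of binomial and Poisson mixed models with
    adaptive Gauss-Hermite quadrature and likelihood-ratio tests; a
    Metropolis-within-Gibbs posterior sampler for the same models;
    posterior transformations to viability-based selection estimates
    (relative fitness cost of inbreeding, egg-weighted selection
    coefficients per cue treatment, genotype-level care-survival
    covariance); and a two-habitat metapopulation model of genetic load at
    mutation-selection balance under soft selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    lme4,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
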