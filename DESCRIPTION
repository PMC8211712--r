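Package: karstrad
Title: Diagnosing Adaptive Radiation on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to diagnose adaptive radiation on an ultrametric,
    time-calibrated phylogeny. Implements lineage-through-time analysis and
    the gamma statistic with Monte-Carlo pure-birth nulls; maximum-likelihood
    fitting and Akaike-weight comparison of constant-rate, diversity-dependent
    and time-shifted birth-death models; Mk-model fitting, stochastic
    character mapping and changes-through-time curves for discrete habitat
    evolution; disparity-through-time curves, the morphological disparity
    index and rank envelope tests for continuous traits; phylogenetic size
    correction, phylogenetic PCA, the node height test and Ward clustering;
    multivariate trait-evolution models with a fixed-time mode shift;
    stepwise-AIC detection of convergent adaptive peaks under multi-optimum
    Ornstein-Uhlenbeck evolution; and ancestral geographic reconstruction by
    Brownian motion on sphere-embedded Cartesian coordinates. A synthetic-data
    generator produces trees, discrete and continuous characters and
    geography with the statistical structure the analyses assume, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
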