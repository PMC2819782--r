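Package: prevfactor
Title: Small-Area Disease Prevalence from Aggregated Totals via a Shared
    Spatial Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates chronic-disease prevalence for small areas when
    prevalence totals are observed only for larger administrative units,
    by pooling small-area collateral indicators of morbidity (deaths,
    hospitalisations) through a shared spatially correlated latent factor.
    The latent factor follows a Leroux-type conditional autoregressive
    prior and is regressed on observed area risk factors (a spatial
    multiple-indicators multiple-causes structure). Aggregated prevalence
    totals are disaggregated by a Poisson-multinomial equivalence, either
    constrained to reproduce the observed higher-area totals or
    unconstrained. Includes a Metropolis-within-Gibbs sampler, Gelman-Rubin
    convergence checks, DIC model comparison, mixed predictive p-values,
    standardised relative-risk hotspot classification, and a synthetic-data
    generator for two-scale lattice geographies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
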