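Package: malaisetrends
Title: Hierarchical Bayesian Trend Analysis of Malaise-Trap Insect Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating long-term trends in total flying insect
    biomass from interval-aggregated malaise-trap catches. Catch mass is
    modelled as the sum of latent daily biomass values that follow a
    log-normal distribution with a log-linear annual trend, quadratic
    seasonal profile, site random effects and covariate effects; models are
    fitted by adaptive Metropolis-within-Gibbs MCMC with Gelman-Rubin
    convergence checks, DIC model comparison and empirical p-values.
    Includes covariate-preparation stages (spline decomposition and
    spatio-temporal kriging of station weather series, logit-linear
    interpolation of land-use cover, Ellenberg indicator means, Poisson
    mixed-model richness trends), a synthetic-campaign generator with known
    ground truth, and projection of annual, mid-summer and seasonally
    weighted decline statistics with credible intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
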