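# shared fixtures, all generated in code

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    site_id = c("s1", "s1", "s2"),
    year = c(2000L, 2000L, 2001L),
    tau1 = c(100L, 111L, 120L),
    tau2 = c(110L, 121L, 129L),
    mass_g = c(1.0, 2.0, 3.0)
  )
}

tiny_sites <- function() {
  tibble::tibble(site_id = c("s1", "s2"), cluster = c(1L, 2L),
                 lon = c(6.5, 6.8), lat = c(51.0, 51.2), alt_m = c(40, 55))
}

basic_truth <- function(log_lambda = -0.063, v = 0.87, sigma_site = 0.334) {
  model_params(
    c = 2.450, log_lambda = log_lambda,
    beta = c(day = -0.100, day2 = -0.447, cluster2 = 0.420, cluster3 = 0.332),
    sigma2_site = sigma_site^2, v = v
  )
}

# a small campaign with several sites per cluster (keeps every design
# column identifiable at small n)
small_config <- function(seed, n_sites = 12, years = 2000:2005,
                         truth = basic_truth(), ...) {
  generator_config(
    n_sites = n_sites, years = years,
    resample_pattern = stats::setNames(c(n_sites / 2, n_sites / 2), c(1, 2)),
    cluster_probabilities = c(0.45, 0.45, 0.10),
    truth = truth, seed = seed, ...
  )
}

# a biomass_fit with hand-specified posterior draws, for closed-form
# projection checks. draws: named list of vectors (recycled to n_draws);
# design columns absent from the list default to 0.
fake_fit <- function(design, draws, n_draws = 50) {
  pars <- c("c", colnames(design$X), paste0("u_", design$site_levels),
            "sigma_site", "v", "deviance")
  M <- matrix(0, n_draws, length(pars), dimnames = list(NULL, pars))
  for (nm in names(draws)) M[, nm] <- rep_len(draws[[nm]], n_draws)
  half <- n_draws %/% 2
  structure(list(
    chains = list(M[seq_len(half), , drop = FALSE],
                  M[(half + 1):n_draws, , drop = FALSE]),
    parameters = pars,
    spec = design$spec,
    design = design,
    record = design$record,
    config = NULL,
    acceptance = NULL,
    posterior_mu = rep(1, design$n_samples),
    rhat = tibble::tibble(parameter = pars, rhat = 1),
    runtime_s = 0
  ), class = "biomass_fit")
}

# brute-force likelihood oracle: per-day loop, no shared code with the
# package internals beyond the parameter definition
oracle_loglik <- function(params, samples, sites, X, day_sample) {
  theta <- c(params$c, vapply(colnames(X), function(cn) {
    if (cn == "year") return(params$log_lambda)
    b <- params$beta[cn]
    if (is.na(b)) 0 else unname(b)
  }, numeric(1)))
  ll <- 0
  for (j in seq_len(nrow(samples))) {
    rows <- which(day_sample == j)
    u <- params$u[[samples$site_id[j]]]
    if (is.null(u) || is.na(u)) u <- 0
    mu <- 0; s2 <- 0
    for (r in rows) {
      y <- theta[1] + sum(X[r, ] * theta[-1]) + u
      mu <- mu + exp(y)
      s2 <- s2 + exp(2 * y + params$v) * (exp(params$v) - 1)
    }
    ll <- ll - 0.5 * log(2 * pi * s2) - (samples$mass_g[j] - mu)^2 / (2 * s2)
  }
  as.numeric(ll)
}
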