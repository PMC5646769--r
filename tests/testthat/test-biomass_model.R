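test_that("model specs reproduce the analysis-ladder column patterns", {
  expect_setequal(spec_columns(model_spec("null")),
                  c("day", "day2", "cluster2", "cluster3"))
  b <- spec_columns(model_spec("basic"))
  expect_setequal(b, c("day", "day2", "cluster2", "cluster3", "year",
                       "year:day", "year:day2"))
  # parameter counts including the intercept match the ladder: 5, 8, 13,
  # 15, 12, 16, 23
  npar <- vapply(c("null", "basic", "weather", "habitat", "landuse",
                   "landuse_interactions", "final"),
                 function(nm) length(spec_columns(model_spec(nm))) + 1L,
                 integer(1))
  expect_equal(unname(npar), c(5L, 8L, 13L, 15L, 12L, 16L, 23L))
  expect_error(model_spec("frobnicate"), "unknown")
})

test_that("daily log-mean is the linear predictor of the latent state", {
  X0 <- matrix(0, 1, 2, dimnames = list(NULL, c("day", "year")))
  p <- model_params(c = 2.450)
  expect_equal(daily_log_mean(p, X0), 2.450)
  expect_equal(exp(daily_log_mean(p, X0)), 11.58835, tolerance = 1e-6)

  X1 <- matrix(c(0, 1), 1, 2, dimnames = list(NULL, c("day", "year")))
  p2 <- model_params(c = 0, log_lambda = -0.080)
  expect_equal(daily_log_mean(p2, X1), -0.080)

  p3 <- model_params(c = 1, u = c(s1 = 0.334))
  expect_equal(daily_log_mean(p3, X0, site = "s1"), 1.334)
  expect_equal(daily_log_mean(p3, X0, site = "s9"), 1) # unknown site: u = 0
  expect_error(daily_log_mean(model_params(c = 0, beta = c(bogus = 1)), X1),
               "bogus")
})

test_that("daily variance follows the log-normal method of moments", {
  expect_equal(daily_variance(1.3, 0), 0)
  expect_equal(daily_variance(0, 0.870), 3.310433, tolerance = 1e-6)
  expect_error(daily_variance(0, -0.1), ">= 0")

  # Monte-Carlo oracle over random (y, v) pairs
  set.seed(42)
  for (i in 1:20) {
    y <- runif(1, -1, 2); v <- runif(1, 0.05, 1)
    draws <- exp(rnorm(1e5, y, sqrt(v)))
    emp_var <- var(draws)
    se <- sd((draws - mean(draws))^2) / sqrt(length(draws))
    expect_lt(abs(daily_variance(y, v) - emp_var), 3 * se)
  }
})

test_that("sample moments sum the exposure interval inclusively", {
  s <- tiny_samples()
  des <- build_design(s, tiny_sites(), model_spec("null"))
  p <- model_params(c = 0.5, beta = c(day = 0.2, day2 = -0.3, cluster2 = 0.1,
                                      cluster3 = 0), v = 0.4)
  mom <- sample_moments(p, des)
  # brute-force day loop
  for (j in 1:3) {
    rows <- which(des$day_sample == j)
    y <- 0.5 + des$X[rows, , drop = FALSE] %*% c(0.2, -0.3, 0.1, 0)
    expect_equal(mom$mu[j], sum(exp(y)), tolerance = 1e-12)
    expect_equal(mom$sigma2[j], sum(exp(2 * y + 0.4) * (exp(0.4) - 1)),
                 tolerance = 1e-12)
  }
  # a 10-day interval with constant covariates is 10 x the one-day value
  s10 <- tibble::tibble(sample_id = c("one", "ten"), site_id = "s1",
                        year = 2000L, tau1 = c(100L, 101L), tau2 = c(100L, 110L),
                        mass_g = 1)
  spec1 <- model_spec("custom", main = c("cluster2", "cluster3", "year"))
  des10 <- build_design(s10, tiny_sites(), spec1)
  m10 <- sample_moments(model_params(c = 1, v = 0.3), des10)
  expect_equal(m10$mu[2], 10 * m10$mu[1], tolerance = 1e-12)
  expect_equal(m10$sigma2[2], 10 * m10$sigma2[1], tolerance = 1e-12)
})

test_that("log-likelihood equals the brute-force oracle", {
  # single sample at its mean: log-density is the normal mode
  s1 <- tibble::tibble(sample_id = "a", site_id = "s1", year = 2000L,
                       tau1 = 100L, tau2 = 105L, mass_g = 0)
  spec <- model_spec("null")
  des1 <- build_design(s1, tiny_sites(), spec)
  p <- model_params(c = 1, beta = c(day = -0.1, day2 = -0.4, cluster2 = 0,
                                    cluster3 = 0), v = 0.6)
  mom <- sample_moments(p, des1)
  s1$mass_g <- mom$mu
  des1 <- build_design(s1, tiny_sites(), spec)
  expect_equal(log_likelihood(p, des1), -0.5 * log(2 * pi * mom$sigma2),
               tolerance = 1e-12)

  # additivity over independent samples and full oracle on a random fixture
  sim <- generate_dataset(small_config(seed = 61, n_sites = 6, years = 2000:2002))
  sub <- sim$samples[1:20, ]
  des <- build_design(sub, sim$sites, model_spec("basic"))
  params <- basic_truth()
  params$u <- setNames(rnorm(6, 0, 0.3), sim$sites$site_id)
  ll <- log_likelihood(params, des)
  oracle <- oracle_loglik(params, sub, sim$sites, des$X, des$day_sample)
  expect_equal(ll, oracle, tolerance = 1e-9)

  one <- log_likelihood(params, build_design(sub[1, ], sim$sites,
                                             model_spec("basic")))
  # additivity needs identical standardization, so compare within one design
  lls <- vapply(1:20, function(j) {
    d <- des; keep <- des$day_sample == j
    d$X <- des$X[keep, , drop = FALSE]
    d$mass <- des$mass[j]; d$samples <- des$samples[j, ]
    d$n_samples <- 1L
    d$day_sample <- rep(1L, sum(keep)); d$sample_len <- sum(keep)
    d$sample_ends <- sum(keep)
    d$sample_site <- des$sample_site[j]; d$day_site <- des$day_site[keep]
    log_likelihood(params, d)
  }, numeric(1))
  expect_equal(sum(lls), ll, tolerance = 1e-9)
  expect_error(log_likelihood(model_params(c = 1, beta = params$beta,
                                           log_lambda = 0, v = 0), des),
               "non-positive")
})

test_that("missing covariate days are reported by name", {
  s <- tiny_samples()
  spec <- model_spec("custom", main = c("temperature", "cluster2", "cluster3",
                                        "year"))
  daily <- tidyr::expand_grid(site_id = c("s1", "s2"), year = 2000:2001,
                              doy = 100:128) |>
    dplyr::mutate(temperature = 10)
  expect_error(build_design(s, tiny_sites(), spec, daily = daily),
               "day 129")
})

test_that("psrf is 1 for identical chains and large for separated chains", {
  set.seed(1)
  v <- rnorm(1000)
  same <- list(cbind(x = v), cbind(x = v))
  # classical estimator: identical chains give sqrt((n-1)/n), i.e. 1 to
  # within 1/(2n)
  expect_equal(psrf(same)$rhat, 1, tolerance = 1e-3)
  indep <- list(cbind(x = rnorm(1000)), cbind(x = rnorm(1000)),
                cbind(x = rnorm(1000)))
  expect_lt(psrf(indep)$rhat, 1.02)
  apart <- list(cbind(x = rnorm(500)), cbind(x = rnorm(500, mean = 8)))
  expect_gt(psrf(apart)$rhat, 3)
  expect_error(psrf(list(cbind(x = v))), "2 chains")
})

test_that("DIC uses half the deviance variance as effective parameters", {
  expect_equal(dic(rep(100, 50))$pd, 0)
  expect_equal(dic(rep(100, 50))$dic, 100)
  set.seed(7)
  dev <- rnorm(20000, 500, sqrt(30))
  d <- dic(dev)
  expect_equal(d$pd, 15, tolerance = 0.08)
  expect_equal(d$mean_deviance, 500, tolerance = 0.01)
  expect_error(dic(rnorm(5)), "10 deviance")
})

test_that("empirical p-values are two-sided posterior tail fractions", {
  expect_equal(empirical_pvalue(runif(200) + 0.01), 0)
  set.seed(3)
  expect_equal(empirical_pvalue(rnorm(2e5)), 1, tolerance = 0.02)
  expect_equal(empirical_pvalue(rnorm(2e5, 1.96, 1)), 0.05, tolerance = 0.006)
  expect_error(empirical_pvalue(rnorm(50)), "100 draws")
})

test_that("MCMC recovers truth in the near-deterministic limit", {
  truth <- basic_truth(log_lambda = -0.05, v = 0.01, sigma_site = 0)
  sim <- generate_dataset(small_config(seed = 71, n_sites = 8,
                                       years = 2000:2004, truth = truth))
  # the generating limit has no site heterogeneity, so the site-sd prior is
  # pinned near zero to match
  fit <- suppressWarnings(fit_mcmc(sim$samples, sim$sites, model_spec("basic"),
                                   config = mcmc_config(n_iter = 5000, n_burn = 2000,
                                                        thin = 4, seed = 5,
                                                        sigma_site_bound = 0.01)))
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "c"] - 2.450), 0.02)
  expect_lt(abs(est$estimate[est$term == "year"] - (-0.05)), 0.02)
})

test_that("site effects shrink to zero when the site-sd prior bound vanishes", {
  sim <- generate_dataset(small_config(seed = 81, n_sites = 6, years = 2000:2002))
  fit <- suppressWarnings(fit_mcmc(
    sim$samples, sim$sites, model_spec("null"),
    config = mcmc_config(n_iter = 1200, n_burn = 400, thin = 4, seed = 5,
                         sigma_site_bound = 1e-3)))
  umax <- max(abs(tidy(fit, effects = "random")$estimate))
  expect_lt(umax, 0.01)
})

test_that("a clear trend is preferred by DIC over the null model", {
  cfg91 <- generator_config(
    n_sites = 16, years = 2000:2009,
    resample_pattern = c("2" = 8, "3" = 8),
    cluster_probabilities = c(0.45, 0.45, 0.10),
    truth = basic_truth(log_lambda = -0.08), seed = 91)
  sim <- generate_dataset(cfg91)
  cfg <- function(s) mcmc_config(n_iter = 3000, n_burn = 1000, thin = 4, seed = s)
  fit_null <- suppressWarnings(fit_mcmc(sim$samples, sim$sites, model_spec("null"),
                                        config = cfg(31)))
  fit_basic <- suppressWarnings(fit_mcmc(sim$samples, sim$sites, model_spec("basic"),
                                         config = cfg(32)))
  expect_gt(dic(fit_null)$dic - dic(fit_basic)$dic, 20)
})
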