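#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-rank) between/within-chain variance ratio: with `m` chains
#' of length `n`, `W` the mean within-chain variance and `B/n` the variance
#' of chain means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`.  Values near 1
#' indicate the chains have mixed.
#'
#' @param x A `biomass_fit`, or a list/matrix of chains (columns =
#'   parameters, or a list of numeric vectors for a single parameter).
#' @param parameter Optional parameter name(s) to restrict to.
#' @return Tibble with columns `parameter`, `rhat`.
#' @export
psrf <- function(x, parameter = NULL) {
  chains <- if (inherits(x, "biomass_fit")) x$chains
  else if (is.list(x)) x
  else abort("x must be a biomass_fit or a list of chains")
  if (length(chains) < 2L) abort("psrf needs at least 2 chains")
  if (is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(v) matrix(v, ncol = 1,
                                                dimnames = list(NULL, "x")))
  }
  pars <- parameter %||% colnames(chains[[1]])
  n <- min(vapply(chains, nrow, integer(1)))
  rh <- vapply(pars, function(p) {
    cs <- lapply(chains, function(M) M[seq_len(n), p])
    W <- mean(vapply(cs, var, numeric(1)))
    B_n <- var(vapply(cs, mean, numeric(1)))
    if (!is.finite(W) || W == 0) return(if (isTRUE(B_n == 0)) 1 else Inf)
    sqrt(((n - 1) / n * W + B_n) / W)
  }, numeric(1))
  tibble::tibble(parameter = pars, rhat = unname(rh))
}

#' Deviance information criterion
#'
#' `pD = var(deviance draws) / 2` and `DIC = mean(deviance) + pD` (the
#' convention of common Gibbs-sampler front ends).  The alternative
#' `pD = mean(deviance) - deviance(posterior means)` is available with
#' `pd_method = "mean"`.
#'
#' @param x A `biomass_fit`, or a numeric vector of deviance draws.
#' @param pd_method `"var"` (default) or `"mean"`; `"mean"` requires a
#'   `biomass_fit` (the deviance at the posterior-mean parameters is
#'   recomputed from the stored design).
#' @return One-row tibble: `dic`, `pd`, `mean_deviance`.
#' @export
dic <- function(x, pd_method = c("var", "mean")) {
  pd_method <- match.arg(pd_method)
  dev <- if (inherits(x, "biomass_fit")) draws_matrix(x, "deviance")[, 1]
  else as.numeric(x)
  if (length(dev) < 10L) abort("dic needs at least 10 deviance draws")
  dbar <- mean(dev)
  pd <- if (pd_method == "var") {
    var(dev) / 2
  } else {
    if (!inherits(x, "biomass_fit")) abort("pd_method = 'mean' needs a biomass_fit")
    dhat <- -2 * log_likelihood(posterior_mean_params(x), x$design)
    dbar - dhat
  }
  tibble::tibble(dic = dbar + pd, pd = pd, mean_deviance = dbar)
}

#' Empirical two-sided posterior p-value
#'
#' `p = 2 * min(Pr(draw > 0), Pr(draw < 0))`, capped at 1.  Draws exactly at
#' zero count to neither side.  A returned 0 means no draw crossed zero,
#' i.e. p < 1/(number of draws).
#'
#' @param x A `biomass_fit` or a numeric vector of posterior draws.
#' @param parameter Parameter name when `x` is a fit.
#' @return Scalar p-value.
#' @export
empirical_pvalue <- function(x, parameter = NULL) {
  v <- if (inherits(x, "biomass_fit")) {
    if (is.null(parameter)) abort("give `parameter` with a biomass_fit")
    draws_matrix(x, parameter)[, 1]
  } else as.numeric(x)
  if (length(v) < 100L) abort("empirical_pvalue needs at least 100 draws")
  min(1, 2 * min(mean(v > 0), mean(v < 0)))
}

#' Squared correlation between observed and fitted log biomass
#'
#' Squared Pearson correlation between `log` of the observed catch masses
#' and `log` of the posterior-mean expected catch masses.  Catches with
#' non-positive recorded mass are dropped from the correlation.
#'
#' @param fit A `biomass_fit`.
#' @return Scalar R².
#' @export
fit_r_squared <- function(fit) {
  m <- fit$design$mass
  mu <- fit$posterior_mu
  ok <- m > 0 & mu > 0
  cor(log(m[ok]), log(mu[ok]))^2
}

#' Convergence and model-comparison report
#'
#' @param fit A `biomass_fit`.
#' @return List with `rhat` (tibble), `acceptance`, `dic` (tibble),
#'   `r_squared`, `n_draws`.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "biomass_fit"))
  list(rhat = fit$rhat,
       acceptance = fit$acceptance,
       dic = dic(fit),
       r_squared = fit_r_squared(fit),
       n_draws = nrow(draws_matrix(fit)))
}
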