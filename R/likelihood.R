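#' Expected daily log-biomass
#'
#' The linear predictor of the latent daily state: intercept + annual trend
#' × year index + covariate effects + site random effect.  `exp()` of the
#' result is the expected daily biomass in grams per day.
#'
#' @param params A [model_params()] object.
#' @param X Design rows: a numeric matrix (or data frame) whose columns are
#'   named design columns on the fitted (standardized) scale, e.g. from
#'   [design_newdata()].
#' @param site Optional vector of site ids (one per row of `X`) whose random
#'   effects `params$u` are added; sites without an entry in `u` get 0.
#' @return Numeric vector of daily log-biomass values (log g/day).
#' @examples
#' p <- model_params(c = 2.450)
#' daily_log_mean(p, matrix(0, 1, 1, dimnames = list(NULL, "day")))
#' @export
daily_log_mean <- function(params, X, site = NULL) {
  X <- as.matrix(X)
  theta <- param_vector(params, colnames(X))
  y <- params$c + drop(X %*% theta)
  if (!is.null(site)) {
    if (length(site) != nrow(X)) abort("`site` must have one entry per row of X")
    u <- params$u[as.character(site)]
    u[is.na(u)] <- 0
    y <- y + unname(u)
  }
  y
}

#' Variance of daily biomass from the log-scale residual variance
#'
#' Method-of-moments variance of a log-normal variable with log-location
#' `y` and log-variance `v`: `exp(2y + v) * (exp(v) - 1)`, in grams squared.
#'
#' @param y Daily log-biomass (log g/day).
#' @param v Residual variance of daily log-biomass; must be `>= 0`.
#' @return Daily biomass variance, g².
#' @examples
#' daily_variance(0, 0.870) # exp(0.87) * (exp(0.87) - 1)
#' @export
daily_variance <- function(y, v) {
  if (any(v < 0)) abort("v must be >= 0")
  exp(2 * y + v) * (exp(v) - 1)
}

# per-sample sums of a day-level vector; day rows are grouped contiguously
# by sample, so cumulative sums at the sample end indices do it in O(n)
sample_sums <- function(x, ends) {
  diff(c(0, cumsum(x)[ends]))
}

#' Per-sample moments of the interval-aggregated catch
#'
#' For each catch, the mean is the sum of expected daily biomass over the
#' inclusive exposure interval and the variance is the sum of the daily
#' biomass variances.
#'
#' @param params A [model_params()] object.
#' @param design A [build_design()] result.
#' @return Tibble with one row per sample: `sample_id`, `mu` (g), `sigma2`
#'   (g²).
#' @export
sample_moments <- function(params, design) {
  stopifnot(inherits(design, "biomass_design"))
  y <- daily_log_mean(params, design$X,
                      site = design$site_levels[design$day_site])
  z <- exp(y)
  s2 <- daily_variance(y, params$v)
  tibble::tibble(
    sample_id = design$samples$sample_id,
    mu = sample_sums(z, design$sample_ends),
    sigma2 = sample_sums(s2, design$sample_ends)
  )
}

#' Log-likelihood of the catch masses
#'
#' Sum over samples of the normal log-density of the observed mass at the
#' interval-aggregated mean and variance.
#'
#' @inheritParams sample_moments
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, design) {
  mom <- sample_moments(params, design)
  if (any(mom$sigma2 <= 0)) {
    abort(sprintf("non-positive sample variance (v = %g) for sample %s",
                  params$v, mom$sample_id[which(mom$sigma2 <= 0)[1]]))
  }
  ll <- dnorm(design$mass, mom$mu, sqrt(mom$sigma2), log = TRUE)
  if (any(!is.finite(ll))) {
    abort(sprintf("non-finite log-likelihood for sample %s",
                  mom$sample_id[which(!is.finite(ll))[1]]))
  }
  sum(ll)
}
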