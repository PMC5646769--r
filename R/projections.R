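#' Percent decline implied by a log-scale annual trend coefficient
#'
#' `100 * (1 - exp(coef * n_years))`: a negative coefficient gives a
#' positive decline percentage.
#'
#' @param coef Annual trend coefficient on the log scale (per year step).
#' @param n_years Number of year steps projected (default 1).
#' @return Percent decline (positive = loss).
#' @examples
#' percent_change_from_coef(-0.063)      # 6.1% annual decline
#' percent_change_from_coef(-0.063, 27)  # decline over 27 years
#' @export
percent_change_from_coef <- function(coef, n_years = 1) {
  if (any(n_years < 1)) abort("n_years must be >= 1")
  100 * (1 - exp(coef * n_years))
}

# map calendar years onto the fitted year coding
year_code_for <- function(record, year) {
  if (identical(record$year_coding, "consecutive")) {
    code <- match(year, record$year_levels)
    if (anyNA(code)) abort(sprintf("year %s outside the fitted year coding",
                                   paste(year[is.na(code)], collapse = ", ")))
    code
  } else {
    as.integer(year - record$year_min + 1L)
  }
}

# draws x days matrix of projected daily biomass (g/day) for one year.
# reference covariates are raw-scale values applied to every day; site
# random effects are integrated out via the log-normal mean factor
# exp(sigma_site^2 / 2) unless integrate_sites = FALSE (then u = 0).
project_draw_matrix <- function(fit, year, window, reference = NULL,
                                integrate_sites = TRUE, zero_trend = FALSE) {
  record <- fit$record
  spec <- fit$spec
  doys <- seq(window[1], window[2])
  extra <- setdiff(spec$main, c("day", "day2", "year", "cluster2", "cluster3"))
  reference <- as.list(reference %||% list())
  cluster <- reference$cluster %||% 1L
  missing <- setdiff(extra, names(reference))
  if (length(missing)) {
    abort(sprintf("projection needs reference values for: %s",
                  paste(missing, collapse = ", ")))
  }
  newdata <- tibble::tibble(doy = doys,
                            year_code = year_code_for(record, year),
                            cluster = as.integer(cluster))
  for (cn in extra) newdata[[cn]] <- reference[[cn]]
  Xn <- design_newdata(record, newdata)

  Theta <- draws_matrix(fit, c("c", colnames(fit$design$X)))
  if (zero_trend && "year" %in% colnames(Theta)) Theta[, "year"] <- 0
  logz <- Theta %*% t(cbind(1, Xn))
  if (integrate_sites) {
    sig <- draws_matrix(fit, "sigma_site")[, 1]
    logz <- logz + sig^2 / 2
  }
  exp(logz)
}

#' Project the seasonal daily biomass curve for one year
#'
#' Evaluates the fitted daily-biomass model on a day grid for a given
#' calendar year, per posterior draw, and summarizes the posterior of the
#' expected daily biomass.  Site random effects are averaged over their
#' fitted distribution (population-level projection) via the log-normal
#' mean factor `exp(sigma_site^2/2)`; set `integrate_sites = FALSE` for a
#' typical-site (`u = 0`) curve.
#'
#' @param fit A `biomass_fit`.
#' @param year Calendar year to project (must lie within the fitted year
#'   coding for `"consecutive"` coding).
#' @param window Inclusive day-of-year range, default 1 April - 30 October
#'   (days 90-302, January 1 = day 0).
#' @param reference Named list of raw-scale covariate values held fixed
#'   across the window (required for every non-temporal covariate of the
#'   spec); `cluster` (1, 2 or 3) defaults to 1.
#' @param integrate_sites Integrate over the site random-effect
#'   distribution (default) or set `u = 0`.
#' @return A `biomass_projection` tibble: `doy`, `estimate` (posterior mean
#'   g/day), `conf.low`, `conf.high` (2.5/97.5% quantiles), with the
#'   per-draw matrix in `attr(, "draws")`.
#' @export
project_season <- function(fit, year, window = c(90L, 302L), reference = NULL,
                           integrate_sites = TRUE) {
  stopifnot(inherits(fit, "biomass_fit"))
  if (window[2] < window[1]) abort("empty projection window")
  Z <- project_draw_matrix(fit, year, window, reference, integrate_sites)
  out <- tibble::tibble(
    doy = seq(window[1], window[2]),
    year = year,
    estimate = colMeans(Z),
    conf.low = apply(Z, 2, quantile, 0.025),
    conf.high = apply(Z, 2, quantile, 0.975)
  )
  attr(out, "draws") <- Z
  class(out) <- c("biomass_projection", class(out))
  out
}

#' Seasonally weighted or peak-day percent decline between two years
#'
#' Projects the daily biomass curve for both years on the same day grid,
#' then per posterior draw forms the ratio of (a) summed daily biomass over
#' the window (`method = "weighted"`, the seasonally weighted decline) or
#' (b) daily biomass at the peak day of the first year's posterior-mean
#' curve (`method = "peak"`, the mid-summer decline).  Decline is
#' `100 * (1 - ratio)`.
#'
#' @inheritParams project_season
#' @param year_from,year_to Calendar years compared (from = baseline).
#' @param method `"weighted"` or `"peak"`.
#' @return One-row tibble: `method`, `year_from`, `year_to`, `estimate`
#'   (posterior mean percent decline), `conf.low`, `conf.high` (2.5/97.5%
#'   posterior quantiles of the decline), with per-draw declines in
#'   `attr(, "draws")`.
#' @export
weighted_decline <- function(fit, year_from, year_to, window = c(90L, 302L),
                             method = c("weighted", "peak"), reference = NULL) {
  method <- match.arg(method)
  Zf <- project_draw_matrix(fit, year_from, window, reference)
  Zt <- project_draw_matrix(fit, year_to, window, reference)
  ratio <- if (method == "weighted") {
    rowSums(Zt) / rowSums(Zf)
  } else {
    peak <- which.max(colMeans(Zf))
    Zt[, peak] / Zf[, peak]
  }
  decline <- 100 * (1 - ratio)
  out <- tibble::tibble(
    method = method, year_from = year_from, year_to = year_to,
    estimate = mean(decline),
    conf.low = quantile(decline, 0.025),
    conf.high = quantile(decline, 0.975)
  )
  attr(out, "draws") <- decline
  out
}

#' Marginal multiplicative effect of an observed covariate change
#'
#' For a coefficient `beta` (standardized design scale) and an observed
#' change `delta` of the covariate over the study period (same scale), the
#' marginal biomass rate is `exp(beta * delta)`.
#'
#' @param beta Coefficient(s), standardized scale.
#' @param delta Observed covariate change(s), standardized scale.
#' @param covariate Optional covariate name(s).
#' @return Tibble: `covariate`, `beta`, `delta`, `rate`, `percent_change`
#'   (100·(rate − 1)).
#' @examples
#' marginal_effect(0.5, 0.2) # rate exp(0.1)
#' @export
marginal_effect <- function(beta, delta, covariate = NULL) {
  rate <- exp(beta * delta)
  tibble::tibble(
    covariate = covariate %||% names(beta) %||% NA_character_,
    beta = unname(beta), delta = unname(delta),
    rate = unname(rate), percent_change = 100 * (unname(rate) - 1)
  )
}

#' Counterfactual biomass change with the annual trend fixed to zero
#'
#' Projects the seasonal biomass for the first and last year with the
#' annual trend coefficient forced to zero while the covariates follow
#' their observed trajectories, and reports the posterior of the ratio
#' (end / start) of summed seasonal biomass — the change attributable to
#' covariate developments alone.
#'
#' @inheritParams project_season
#' @param trajectories Tibble with columns `covariate`, `from`, `to`:
#'   raw-scale covariate values at the start and end of the period.  Every
#'   non-temporal covariate of the spec must be present.
#' @param year_from,year_to Calendar years projected.
#' @return One-row tibble: `rate` (posterior mean of end/start ratio),
#'   `conf.low`, `conf.high`, with per-draw rates in `attr(, "draws")`.
#' @export
counterfactual_no_trend <- function(fit, trajectories, year_from, year_to,
                                    window = c(90L, 302L)) {
  check_columns(trajectories, c("covariate", "from", "to"), "trajectories")
  extra <- setdiff(fit$spec$main, c("day", "day2", "year", "cluster2", "cluster3"))
  missing <- setdiff(extra, trajectories$covariate)
  if (length(missing)) {
    abort(sprintf("missing trajectory for included covariate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ref_from <- as.list(setNames(trajectories$from, trajectories$covariate))
  ref_to <- as.list(setNames(trajectories$to, trajectories$covariate))
  Zf <- project_draw_matrix(fit, year_from, window, ref_from, zero_trend = TRUE)
  Zt <- project_draw_matrix(fit, year_to, window, ref_to, zero_trend = TRUE)
  rate <- rowSums(Zt) / rowSums(Zf)
  out <- tibble::tibble(rate = mean(rate),
                        conf.low = quantile(rate, 0.025),
                        conf.high = quantile(rate, 0.975))
  attr(out, "draws") <- rate
  out
}
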