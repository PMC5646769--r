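#' Tidy posterior summaries of a fitted biomass model
#'
#' One row per parameter: posterior mean, sd, 2.5/97.5% quantiles and the
#' empirical two-sided p-value (location parameters only).
#'
#' @param x A `biomass_fit`.
#' @param effects `"fixed"` (intercept, trend, coefficients, variance
#'   components; default), `"random"` (site effects) or `"all"`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `rhat`.
#' @method tidy biomass_fit
#' @export
tidy.biomass_fit <- function(x, effects = c("fixed", "random", "all"), ...) {
  effects <- match.arg(effects)
  fixed <- c("c", colnames(x$design$X), "sigma_site", "v")
  random <- paste0("u_", x$design$site_levels)
  pars <- switch(effects, fixed = fixed, random = random,
                 all = c(fixed, random))
  M <- draws_matrix(x, pars)
  no_p <- c("sigma_site", "v", random)
  rh <- setNames(x$rhat$rhat, x$rhat$parameter)
  tibble::tibble(
    term = pars,
    estimate = colMeans(M),
    std.error = apply(M, 2, sd),
    conf.low = apply(M, 2, quantile, 0.025),
    conf.high = apply(M, 2, quantile, 0.975),
    p.value = vapply(pars, function(p) {
      if (p %in% no_p) NA_real_ else empirical_pvalue(M[, p])
    }, numeric(1)),
    rhat = unname(rh[pars])
  )
}

#' One-row model summary of a fitted biomass model
#'
#' @param x A `biomass_fit`.
#' @param ... Unused.
#' @return Tibble with `dic`, `pd`, `r.squared`, `max.rhat`, `n.draws`,
#'   `n.samples`, `n.sites`, `annual.decline.pct` (from the posterior-mean
#'   trend coefficient; `NA` for specs without a year term).
#' @method glance biomass_fit
#' @export
glance.biomass_fit <- function(x, ...) {
  d <- dic(x)
  has_year <- "year" %in% colnames(x$design$X)
  loglam <- if (has_year) mean(draws_matrix(x, "year")) else NA_real_
  tibble::tibble(
    dic = d$dic, pd = d$pd,
    r.squared = fit_r_squared(x),
    max.rhat = max(x$rhat$rhat, na.rm = TRUE),
    n.draws = nrow(draws_matrix(x)),
    n.samples = x$design$n_samples,
    n.sites = length(x$design$site_levels),
    annual.decline.pct = if (has_year) percent_change_from_coef(loglam) else NA_real_
  )
}

#' Trace plot of selected parameters
#'
#' @param object A `biomass_fit`.
#' @param parameters Parameter names; defaults to the intercept, trend (if
#'   present) and the two variance components.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot biomass_fit
#' @export
autoplot.biomass_fit <- function(object, parameters = NULL, ...) {
  default <- intersect(c("c", "year", "sigma_site", "v"), object$parameters)
  parameters <- parameters %||% default
  df <- draws_tibble(object) |>
    dplyr::filter(.data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = "value", colour = "chain") +
    ggplot2::theme_minimal()
}

#' Ribbon plot of a projected seasonal biomass curve
#'
#' @param object A `biomass_projection` from [project_season()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot biomass_projection
#' @export
autoplot.biomass_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$doy, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day of year (Jan 1 = 0)", y = "daily biomass (g/day)",
                  title = paste("Projected season,", object$year[1])) +
    ggplot2::theme_minimal()
}

#' Scatter of observed versus fitted catch mass
#'
#' @param fit A `biomass_fit`.
#' @return A ggplot object (log-log scale; non-positive masses dropped).
#' @export
plot_fit_observed <- function(fit) {
  df <- tibble::tibble(observed = fit$design$mass, fitted = fit$posterior_mu) |>
    dplyr::filter(.data$observed > 0, .data$fitted > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "posterior-mean catch mass (g)",
                  y = "observed catch mass (g)") +
    ggplot2::theme_minimal()
}
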