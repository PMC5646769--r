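# Canonical covariate column names.  Day-varying columns come from the
# daily covariate table; the rest are constant within a site-year.
DAY_VARYING <- c("temperature", "precipitation", "wind")
SITE_YEAR_COVARIATES <- c(
  "frost_days", "winter_precip",
  "herb_richness", "tree_richness",
  "ell_nitrogen", "ell_ph", "ell_moisture", "ell_light", "ell_temperature",
  "arable", "grassland", "forest", "water"
)
# Columns never standardized: the year index (small consecutive integers),
# habitat-cluster dummies, land-use fractions (already in [0,1]) and
# interaction products of already-scaled components.
STANDARDIZATION_EXEMPT <- c("year", "cluster2", "cluster3",
                            "arable", "grassland", "forest", "water")

#' Model specification for the biomass observation model
#'
#' Names the fixed-effect structure of one of the seven model variants of
#' the analysis ladder (or a custom set).  All variants share the intercept,
#' a quadratic seasonal profile in day number and the site random effect;
#' they differ in which year, weather, habitat and land-use terms enter the
#' design matrix.
#'
#' @param name One of `"null"`, `"basic"`, `"weather"`, `"habitat"`,
#'   `"landuse"`, `"landuse_interactions"`, `"final"`, or `"custom"`.
#' @param main For `"custom"`: character vector of main-effect columns.
#' @param interactions For `"custom"`: character vector of `"a:b"` products
#'   of main-effect columns.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("basic")
#' @export
model_spec <- function(name, main = NULL, interactions = NULL) {
  base <- c("day", "day2", "cluster2", "cluster3")
  basic_main <- c(base, "year")
  basic_int <- c("year:day", "year:day2")
  spec <- switch(
    name,
    null = list(main = base, interactions = character()),
    basic = list(main = basic_main, interactions = basic_int),
    weather = list(
      main = c(basic_main, "temperature", "precipitation", "wind",
               "frost_days", "winter_precip"),
      interactions = basic_int),
    habitat = list(
      main = c(basic_main, "herb_richness", "tree_richness", "ell_nitrogen",
               "ell_ph", "ell_moisture", "ell_light", "ell_temperature"),
      interactions = basic_int),
    landuse = list(
      main = c(basic_main, "arable", "grassland", "forest", "water"),
      interactions = basic_int),
    landuse_interactions = list(
      main = c(basic_main, "arable", "grassland", "forest", "water"),
      interactions = c(basic_int, "year:arable", "year:forest",
                       "year:water", "year:grassland")),
    final = list(
      main = c("day", "day2", "year", "temperature", "precipitation",
               "frost_days", "cluster2", "cluster3", "arable", "forest",
               "grassland", "water", "herb_richness", "tree_richness",
               "ell_nitrogen", "ell_light", "ell_temperature"),
      interactions = c(basic_int, "year:arable", "year:forest",
                       "year:grassland")),
    custom = {
      if (is.null(main)) abort("custom spec needs `main`")
      list(main = main, interactions = interactions %||% character())
    },
    abort(sprintf("unknown model spec '%s'", name))
  )
  structure(c(list(name = name), spec), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec:", x$name, ">\n")
  cat("  main:        ", paste(x$main, collapse = ", "), "\n")
  cat("  interactions:", if (length(x$interactions))
    paste(x$interactions, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Design column names implied by a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector: main-effect columns followed by interactions.
#' @export
spec_columns <- function(spec) c(spec$main, spec$interactions)

#' Parameter set of the biomass observation model
#'
#' Bundles the global intercept `c` (log grams per day), the annual trend
#' coefficient `log_lambda` (per year step of the year index), the named
#' covariate coefficient vector `beta` (on the standardized design scale),
#' per-site random intercepts `u` (log scale), the site variance
#' `sigma2_site`, and the residual variance of daily log-biomass `v`.
#'
#' @param c Global intercept, log(g/day).
#' @param log_lambda Annual trend coefficient; `exp(log_lambda) - 1` is the
#'   annual proportional change in daily biomass.
#' @param beta Named numeric vector of covariate coefficients (may be empty).
#' @param u Named numeric vector of site random effects (may be empty).
#' @param sigma2_site Variance of the site random effects, `>= 0`.
#' @param v Residual variance of daily log-biomass, `>= 0`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(c = 2.45, log_lambda = -0.063, v = 0.87)
#' @export
model_params <- function(c = 0, log_lambda = 0, beta = numeric(),
                         u = numeric(), sigma2_site = 0, v = 0) {
  if (sigma2_site < 0) abort("sigma2_site must be >= 0")
  if (v < 0) abort("v must be >= 0")
  if (length(beta) && is.null(names(beta))) abort("beta must be named")
  if (length(u) && is.null(names(u))) abort("u must be named")
  structure(list(c = c, log_lambda = log_lambda, beta = beta, u = u,
                 sigma2_site = sigma2_site, v = v),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> c =", format(x$c), " log_lambda =", format(x$log_lambda),
      " sigma2_site =", format(x$sigma2_site), " v =", format(x$v), "\n")
  if (length(x$beta)) {
    cat("  beta:", paste(sprintf("%s=%.3g", names(x$beta), x$beta),
                         collapse = ", "), "\n")
  }
  cat("  u:", length(x$u), "site effect(s)\n")
  invisible(x)
}

# Align a full coefficient vector (c, year -> log_lambda, beta) with the
# design columns.  Columns without a named coefficient get 0; coefficients
# that match no column are an error (they signal a spec/params mismatch).
param_vector <- function(params, columns) {
  unknown <- setdiff(names(params$beta), columns)
  if (length(unknown)) {
    abort(sprintf("coefficient(s) %s match no design column",
                  paste(unknown, collapse = ", ")))
  }
  theta <- setNames(numeric(length(columns)), columns)
  if ("year" %in% columns) theta[["year"]] <- params$log_lambda
  hit <- intersect(names(params$beta), columns)
  theta[hit] <- params$beta[hit]
  theta
}
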