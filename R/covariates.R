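#' Logit-linear interpolation of land-cover fractions between survey epochs
#'
#' The cover fraction is interpolated linearly in time on the logit scale
#' and back-transformed, so epoch values are reproduced exactly and the
#' path stays inside (0, 1) — equivalent to the prediction of a saturated
#' two-point binomial GLM with logit link.  Fractions exactly 0 or 1 are
#' shrunk by `1/(2 * n_eff)` before the logit to keep it finite.
#'
#' @param p1,p2 Cover fractions at the two survey epochs, in `[0, 1]`.
#' @param y1,y2 Epoch years, `y1 < y2`.
#' @param target_year Year(s) to interpolate to; years outside `[y1, y2]`
#'   are extrapolated with a warning.
#' @param n_eff Pseudo-trial count used to shrink boundary fractions.
#' @return Interpolated fraction(s).
#' @examples
#' interpolate_cover(0.25, 1990, 0.75, 2014, 2002) # 0.5 by logit symmetry
#' @export
interpolate_cover <- function(p1, y1, p2, y2, target_year, n_eff = 1000) {
  if (any(y2 <= y1)) abort("y1 must be < y2")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) abort("fractions must be in [0, 1]")
  if (any(target_year < y1 | target_year > y2)) {
    warn("target_year outside the survey epochs; extrapolating on the logit scale")
  }
  shrink <- function(p) pmin(1 - 1 / (2 * n_eff), pmax(1 / (2 * n_eff), p))
  l1 <- qlogis(shrink(p1))
  l2 <- qlogis(shrink(p2))
  frac <- (target_year - y1) / (y2 - y1)
  plogis(l1 + frac * (l2 - l1))
}

#' Community-mean Ellenberg indicator values
#'
#' Arithmetic mean of each indicator over the recorded species; species
#' lacking a value for an indicator are skipped for that indicator.
#'
#' @param species Tibble of plant-survey records, one row per species, with
#'   any of the indicator columns.
#' @param indicators Indicator column names to average.
#' @return One-row tibble of per-indicator means (`NaN` where no species
#'   carries the indicator); errors if no species has any value at all.
#' @export
ellenberg_means <- function(species,
                            indicators = c("nitrogen", "ph", "light",
                                           "temperature", "moisture")) {
  present <- intersect(indicators, names(species))
  if (!length(present) || nrow(species) == 0 ||
      all(vapply(present, function(cn) all(is.na(species[[cn]])), logical(1)))) {
    abort("no species with any indicator value")
  }
  out <- lapply(present, function(cn) mean(species[[cn]], na.rm = TRUE))
  names(out) <- present
  tibble::as_tibble(out)
}

#' Annual trend in plant species richness (Poisson mixed model)
#'
#' Fits `richness ~ year + (1 | site_id)` with a Poisson family by Laplace
#' approximation and reports the log-scale year slope, its standard error,
#' and the residual-deviance dispersion diagnostic (values well above 1
#' flag overdispersion, for which the Poisson fit understates uncertainty).
#'
#' @param data Tibble with `site_id`, `year` and `richness` (counts).
#' @param dispersion_flag Dispersion ratio above which `overdispersed` is
#'   set.
#' @return One-row tibble: `slope`, `std.error`, `p.value`, `dispersion`,
#'   `overdispersed`, `n`.
#' @export
richness_trend <- function(data, dispersion_flag = 1.5) {
  check_columns(data, c("site_id", "year", "richness"), "richness data")
  if (dplyr::n_distinct(data$year) < 2) abort("need >= 2 years")
  if (dplyr::n_distinct(data$site_id) < 2) abort("need >= 2 sites")
  if (all(data$richness == 0)) abort("all counts are zero")
  if (dplyr::n_distinct(data$richness) == 1L) {
    # constant counts: the trend is exactly zero and the mixed model is
    # degenerate
    return(tibble::tibble(slope = 0, std.error = NA_real_, p.value = 1,
                          dispersion = 0, overdispersed = FALSE,
                          n = nrow(data)))
  }
  d <- dplyr::mutate(data, year_c = .data$year - mean(.data$year))
  fit <- lme4::glmer(richness ~ year_c + (1 | site_id), data = d,
                     family = stats::poisson())
  sm <- summary(fit)$coefficients
  disp <- sum(stats::residuals(fit, type = "deviance")^2) /
    (nrow(d) - length(lme4::fixef(fit)) - 1L)
  tibble::tibble(
    slope = sm["year_c", "Estimate"],
    std.error = sm["year_c", "Std. Error"],
    p.value = sm["year_c", "Pr(>|z|)"],
    dispersion = disp,
    overdispersed = disp > dispersion_flag,
    n = nrow(d)
  )
}
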