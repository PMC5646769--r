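#' Read malaise-trap catch samples from CSV
#'
#' The samples table holds one row per catch (bottle): an opaque sample and
#' site id, the calendar year, the exposure interval as inclusive
#' day-of-year endpoints (`tau1`, `tau2`, January 1 = day 0) and the wet
#' biomass of the catch in grams.
#'
#' @param path Path to a CSV file with columns
#'   `sample_id, site_id, year, tau1, tau2, mass_g`.
#' @return A tibble of validated trap samples.
#' @seealso [write_samples()], [summarize_samples()]
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(df)
}

#' Validate a samples table
#'
#' Checks the schema and row-level invariants: non-negative mass,
#' `tau1 <= tau2`, exposure within one calendar year, and uniqueness of
#' (site, year, tau1).
#'
#' @param samples Data frame of trap samples.
#' @return The samples as a tibble, invisibly unchanged except for type
#'   coercion of the key columns.
#' @export
validate_samples <- function(samples) {
  check_columns(samples, c("sample_id", "site_id", "year", "tau1", "tau2", "mass_g"),
                "samples table")
  df <- tibble::as_tibble(samples)
  df$year <- as.integer(df$year)
  df$tau1 <- as.integer(df$tau1)
  df$tau2 <- as.integer(df$tau2)
  df$mass_g <- as.numeric(df$mass_g)
  bad <- which(!is.finite(df$mass_g) | df$mass_g < 0)
  if (length(bad)) {
    abort(sprintf("negative or non-finite mass_g at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(df$tau2 < df$tau1)
  if (length(bad)) {
    abort(sprintf("tau2 < tau1 at row(s): %s", paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(df$tau1 < 0L | df$tau2 > 364L)
  if (length(bad)) {
    abort(sprintf("exposure outside one calendar year (day 0..364) at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$site_id, df$year, df$tau1, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (site_id, year, tau1) at row(s): %s",
                  paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  df
}

#' Write samples, sites or covariates to CSV
#'
#' Plain UTF-8 comma-separated files with a header row.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read site records from CSV
#'
#' @param path CSV with columns `site_id, cluster, lon, lat, alt_m`.
#' @return Tibble of site records; `cluster` is one of 1, 2, 3
#'   (nutrient-poor, nutrient-rich, pioneer/shrub vegetation).
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sites(df)
}

#' Validate a sites table
#' @param sites Data frame of site records.
#' @return Tibble of validated site records.
#' @export
validate_sites <- function(sites) {
  check_columns(sites, c("site_id", "cluster", "lon", "lat", "alt_m"), "sites table")
  df <- tibble::as_tibble(sites)
  df$cluster <- as.integer(df$cluster)
  if (!all(df$cluster %in% 1:3)) abort("cluster must be 1, 2 or 3")
  if (!all(is.finite(df$lon) & is.finite(df$lat))) abort("non-finite coordinates")
  if (anyDuplicated(df$site_id)) abort("duplicate site_id")
  df
}

#' Summarize a catch-sample table
#'
#' Totals and exposure bookkeeping for a set of trap samples.  Exposure
#' endpoints are inclusive, so one catch contributes `tau2 - tau1 + 1`
#' exposure days.  The emptying-interval statistics are computed from the
#' differences between successive catch end dates within each site-year
#' (the length of the first catch of a site-year counts as its own
#' interval).
#'
#' @param samples Data frame of trap samples (see [read_samples()]).
#' @return A one-row tibble: `n_samples`, `n_sites`, `n_site_years`,
#'   `total_mass_g`, `total_exposure_days`, `mean_interval_days`,
#'   `sd_interval_days`.
#' @examples
#' s <- tibble::tibble(sample_id = "a", site_id = "s1", year = 2000L,
#'                     tau1 = 100L, tau2 = 110L, mass_g = 2.5)
#' summarize_samples(s)
#' @export
summarize_samples <- function(samples) {
  if (nrow(samples) == 0L) abort("empty samples table")
  df <- validate_samples(samples)
  intervals <- df |>
    dplyr::arrange(.data$site_id, .data$year, .data$tau1) |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::mutate(interval = c(.data$tau2[1] - .data$tau1[1] + 1L,
                               diff(.data$tau2))) |>
    dplyr::ungroup()
  tibble::tibble(
    n_samples = nrow(df),
    n_sites = dplyr::n_distinct(df$site_id),
    n_site_years = dplyr::n_distinct(paste(df$site_id, df$year)),
    total_mass_g = sum(df$mass_g),
    total_exposure_days = sum(df$tau2 - df$tau1 + 1L),
    mean_interval_days = mean(intervals$interval),
    sd_interval_days = sd(intervals$interval)
  )
}

#' Write posterior draws to CSV
#'
#' Long format, one row per kept draw and parameter:
#' `chain, iter, parameter, value`.
#'
#' @param fit A `biomass_fit` object from [fit_mcmc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  readr::write_csv(draws_tibble(fit), path, progress = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path CSV path.
#' @return Tibble with columns `chain, iter, parameter, value`.
#' @export
read_draws <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("chain", "iter", "parameter", "value"), "draws table")
  df
}
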