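#' Default ground-truth parameters for the synthetic campaign
#'
#' Posterior means of the published-scale final model: intercept 2.450 log
#' g/day, annual trend -0.080, standardized day and day² effects -0.100 and
#' -0.447, temperature 0.304, precipitation -0.071, habitat-cluster offsets
#' 0.420 and 0.332, year-by-day interactions -0.003 and 0.010, site sd
#' 0.334 and residual log-scale variance 0.870.
#'
#' @return A [model_params()] object.
#' @export
default_truth <- function() {
  model_params(
    c = 2.450, log_lambda = -0.080,
    beta = c(day = -0.100, day2 = -0.447,
             cluster2 = 0.420, cluster3 = 0.332,
             temperature = 0.304, precipitation = -0.071,
             "year:day" = -0.003, "year:day2" = 0.010),
    sigma2_site = 0.334^2, v = 0.870
  )
}

# model_spec implied by the named coefficients of a truth parameter set
truth_spec <- function(truth) {
  nm <- names(truth$beta)
  model_spec("custom",
             main = c(setdiff(nm[!grepl(":", nm)], character()), "year"),
             interactions = nm[grepl(":", nm, fixed = TRUE)])
}

#' Configuration of the synthetic malaise-trap campaign generator
#'
#' Defaults emulate the study conditions: 63 sites yielding 96 site-year
#' combinations (37 sites sampled in one year, 20 in two, 5 in three, 1 in
#' four), habitat clusters drawn with probabilities 19/63, 41/63, 3/63,
#' trapping from March through October with site-year exposure windows
#' averaging 176 days, catches emptied on average every 11.2 days (sd 6.3).
#'
#' @param n_sites Number of trap sites.
#' @param years Candidate calendar years.
#' @param resample_pattern Named integer vector: how many sites are sampled
#'   in 1, 2, 3, ... years.  Must sum to `n_sites` (scaled proportionally
#'   otherwise).
#' @param cluster_probabilities Probabilities of habitat clusters 1-3.
#' @param season_window Inclusive day-of-year range traps may operate
#'   (default 1 March - 31 October, days 59-303).
#' @param interval_mean_days,interval_sd_days Mean/sd of the catch emptying
#'   interval; lengths are drawn from a normal truncated at 1 day.
#' @param exposure_mean_days,exposure_sd_days Mean/sd of the total site-year
#'   exposure window length (truncated to at least 30 days and at most the
#'   season window).
#' @param truth A [model_params()] ground truth; its named coefficients
#'   determine which covariates enter the forward model.
#' @param seed Integer seed; required.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_sites = 63, years = 1989:2016,
                             resample_pattern = c("1" = 37, "2" = 20, "3" = 5, "4" = 1),
                             cluster_probabilities = c(19, 41, 3) / 63,
                             season_window = c(59L, 303L),
                             interval_mean_days = 11.2, interval_sd_days = 6.3,
                             exposure_mean_days = 176, exposure_sd_days = 45,
                             truth = default_truth(), seed) {
  if (missing(seed) || is.null(seed)) abort("generator_config requires an explicit `seed`")
  if (abs(sum(cluster_probabilities) - 1) > 1e-8 || any(cluster_probabilities < 0)) {
    abort("cluster_probabilities must be a 3-simplex")
  }
  if (interval_mean_days <= 0) abort("interval_mean_days must be positive")
  if (season_window[1] < 0 || season_window[2] > 364 ||
      season_window[2] < season_window[1]) {
    abort("season_window must be an increasing day range within one year")
  }
  if (truth$v < 0 || truth$sigma2_site < 0) abort("truth variances must be >= 0")
  structure(list(
    n_sites = as.integer(n_sites), years = as.integer(years),
    resample_pattern = resample_pattern,
    cluster_probabilities = cluster_probabilities,
    season_window = as.integer(season_window),
    interval_mean_days = interval_mean_days,
    interval_sd_days = interval_sd_days,
    exposure_mean_days = exposure_mean_days,
    exposure_sd_days = exposure_sd_days,
    truth = truth, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate trap sites
#'
#' Sites are placed uniformly in a lowland bounding box (6.0-7.5 E,
#' 50.7-52.0 N, altitude 20-100 m) with habitat clusters drawn from the
#' configured probabilities.
#'
#' @param config A [generator_config()].
#' @return Sites tibble (`site_id, cluster, lon, lat, alt_m`).
#' @export
generate_sites <- function(config) {
  if (config$n_sites < 1) abort("n_sites must be >= 1")
  set.seed(config$seed)
  n <- config$n_sites
  tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n)),
    cluster = sample.int(3L, n, replace = TRUE, prob = config$cluster_probabilities),
    lon = runif(n, 6.0, 7.5),
    lat = runif(n, 50.7, 52.0),
    alt_m = runif(n, 20, 100)
  )
}

#' Generate one site-year's catch exposure schedule
#'
#' Contiguous inclusive intervals tiling the window.  Interval lengths are
#' drawn from a normal truncated at one day whose parent parameters are
#' moment-matched so the truncated distribution has the configured mean and
#' sd, then rounded to whole days.  The final interval is cut at the window
#' end.
#'
#' @param config A [generator_config()].
#' @param window Inclusive day-of-year range to tile (defaults to the
#'   config's season window).
#' @param seed Optional seed (the dataset generator seeds globally instead).
#' @return Tibble of intervals (`tau1`, `tau2`).
#' @export
generate_exposure_schedule <- function(config, window = config$season_window,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (window[2] < window[1]) abort("empty window")
  par <- if (config$interval_sd_days > 0) {
    truncnorm_match(config$interval_mean_days, config$interval_sd_days, 1)
  }
  tau1 <- integer(0); tau2 <- integer(0)
  start <- window[1]
  while (start <= window[2]) {
    len <- if (config$interval_sd_days == 0) {
      max(1L, as.integer(round(config$interval_mean_days)))
    } else {
      max(1L, as.integer(round(rtruncnorm_lower(
        1, par["mu"], par["sigma"], 1))))
    }
    stop_day <- min(start + len - 1L, window[2])
    tau1 <- c(tau1, start); tau2 <- c(tau2, as.integer(stop_day))
    start <- stop_day + 1L
  }
  tibble::tibble(tau1 = tau1, tau2 = tau2)
}

# assign each site its sampled years and exposure window
generate_site_years <- function(config, sites) {
  pat <- config$resample_pattern
  counts <- as.integer(pat)
  times <- as.integer(names(pat))
  if (sum(counts) == config$n_sites) {
    n_years_per_site <- sample(rep(times, counts))
  } else {
    n_years_per_site <- sample(times, config$n_sites, replace = TRUE,
                               prob = counts / sum(counts))
  }
  win_len_max <- config$season_window[2] - config$season_window[1] + 1L
  purrr::map2_dfr(sites$site_id, n_years_per_site, function(sid, k) {
    yrs <- sort(sample(config$years, min(k, length(config$years))))
    L <- pmin(win_len_max,
              pmax(30L, as.integer(round(rnorm(length(yrs),
                                               config$exposure_mean_days,
                                               config$exposure_sd_days)))))
    off <- vapply(win_len_max - L, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
    tibble::tibble(site_id = sid, year = yrs,
                   win1 = config$season_window[1] + off,
                   win2 = config$season_window[1] + off + L - 1L)
  })
}

# daily weather covariates: seasonal sinusoid + AR(1) anomalies
generate_daily_covariates <- function(site_years) {
  purrr::pmap_dfr(site_years, function(site_id, year, win1, win2) {
    d <- seq(win1, win2)
    n <- length(d)
    ar1 <- function(n, phi, sd) {
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
      for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, sd)
      x
    }
    tibble::tibble(
      site_id = site_id, year = year, doy = d,
      temperature = 10 + 8 * cos(2 * pi * (d - 196) / 365) + ar1(n, 0.7, 1.5),
      precipitation = pmax(0, 2 + sin(2 * pi * (d - 150) / 365) + ar1(n, 0.4, 2)),
      wind = pmax(0.2, 3 - 0.8 * cos(2 * pi * (d - 196) / 365) + ar1(n, 0.5, 0.8))
    )
  })
}

# site-year covariates: Dirichlet land-use shares, cluster-structured
# habitat indicators, winter weather summaries
generate_site_year_covariates <- function(site_years, sites) {
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), alpha, 1)
    g / sum(g)
  }
  lu <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    f <- rdirichlet1(c(2, 3, 3, 0.5, 1.5))
    tibble::tibble(site_id = sites$site_id[i],
                   arable = f[1], grassland = f[2], forest = f[3], water = f[4])
  })
  herb_mu <- c(22, 32, 18); tree_mu <- c(4, 7, 5)
  ell_mu <- list(n = c(3.5, 6.0, 4.5), ph = c(4.5, 6.5, 5.5),
                 light = c(7.2, 6.8, 7.0), temp = c(5.4, 5.6, 5.5),
                 moist = c(4.5, 5.2, 5.0))
  cl <- sites$cluster[match(site_years$site_id, sites$site_id)]
  n <- nrow(site_years)
  clip19 <- function(x) pmin(9, pmax(1, x))
  tibble::tibble(
    site_id = site_years$site_id, year = site_years$year,
    frost_days = rpois(n, 30),
    winter_precip = pmax(0, rnorm(n, 250, 50)),
    herb_richness = rpois(n, herb_mu[cl]),
    tree_richness = rpois(n, tree_mu[cl]),
    ell_nitrogen = clip19(rnorm(n, ell_mu$n[cl], 0.3)),
    ell_ph = clip19(rnorm(n, ell_mu$ph[cl], 0.3)),
    ell_light = clip19(rnorm(n, ell_mu$light[cl], 0.2)),
    ell_temperature = clip19(rnorm(n, ell_mu$temp[cl], 0.15)),
    ell_moisture = clip19(rnorm(n, ell_mu$moist[cl], 0.3))
  ) |>
    dplyr::left_join(lu, by = "site_id")
}

#' Generate a complete synthetic malaise-trap campaign
#'
#' Forward-simulates the observation model with known ground truth: sites,
#' site-year exposure windows and emptying schedules, daily and site-year
#' covariates, latent daily biomass from the truth parameters (with the
#' same design construction and standardization the fitting stage uses) and
#' finally catch masses drawn normal about the interval sums and clipped at
#' zero.  The clipped fraction is reported in the truth record; the fitting
#' likelihood keeps the untruncated normal.
#'
#' @param config A [generator_config()].
#' @return A `malaise_sim` list: `samples`, `sites`, `daily`, `site_year`,
#'   and `truth` (truth parameters with realized site effects, per-sample
#'   `mu`/`sigma2`, clipped fraction and seed).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sites <- generate_sites(config) # seeds the RNG with config$seed
  site_years <- generate_site_years(config, sites)
  schedules <- purrr::pmap_dfr(site_years, function(site_id, year, win1, win2) {
    sch <- generate_exposure_schedule(config, window = c(win1, win2))
    sch$site_id <- site_id; sch$year <- year
    sch
  })
  samples <- schedules |>
    dplyr::mutate(sample_id = sprintf("%s-%d-%02d", .data$site_id, .data$year,
                                      dplyr::row_number()),
                  .by = c("site_id", "year")) |>
    dplyr::mutate(mass_g = 0) |>
    dplyr::select("sample_id", "site_id", "year", "tau1", "tau2", "mass_g")

  daily <- generate_daily_covariates(site_years)
  site_year <- generate_site_year_covariates(site_years, sites)

  spec <- truth_spec(config$truth)
  design <- build_design(samples, sites, spec, daily = daily,
                         site_year = site_year, year_coding = "calendar")

  u <- rnorm(config$n_sites, 0, sqrt(config$truth$sigma2_site))
  names(u) <- sites$site_id
  params <- config$truth
  params$u <- u

  mom <- sample_moments(params, design)
  raw_mass <- rnorm(nrow(samples), mom$mu, sqrt(mom$sigma2))
  clipped <- raw_mass < 0
  samples$mass_g <- pmax(0, raw_mass)

  truth <- structure(list(
    params = params,
    spec = spec,
    sample_moments = mom,
    clipped_fraction = mean(clipped),
    site_years = site_years,
    seed = config$seed
  ), class = "malaise_truth")

  structure(list(samples = samples, sites = sites, daily = daily,
                 site_year = site_year, truth = truth),
            class = "malaise_sim")
}

#' @export
print.malaise_sim <- function(x, ...) {
  s <- summarize_samples(x$samples)
  cat("<malaise_sim>", s$n_samples, "samples,", s$n_sites, "sites,",
      s$n_site_years, "site-years; clipped fraction",
      format(x$truth$clipped_fraction, digits = 3), "\n")
  invisible(x)
}

#' Write / read a truth record as JSON
#'
#' @param truth A `malaise_truth` record.
#' @param path JSON path.
#' @return `path` (write) or the truth record (read).
#' @export
write_truth <- function(truth, path) {
  x <- list(
    params = list(c = truth$params$c, log_lambda = truth$params$log_lambda,
                  beta = as.list(truth$params$beta),
                  u = as.list(truth$params$u),
                  sigma2_site = truth$params$sigma2_site, v = truth$params$v),
    spec = list(name = truth$spec$name, main = truth$spec$main,
                interactions = truth$spec$interactions),
    sample_moments = truth$sample_moments,
    clipped_fraction = truth$clipped_fraction,
    seed = truth$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    params = model_params(c = x$params$c, log_lambda = x$params$log_lambda,
                          beta = unlist(x$params$beta),
                          u = unlist(x$params$u),
                          sigma2_site = x$params$sigma2_site, v = x$params$v),
    spec = model_spec("custom", main = x$spec$main,
                      interactions = x$spec$interactions),
    sample_moments = tibble::as_tibble(x$sample_moments),
    clipped_fraction = x$clipped_fraction,
    seed = x$seed
  ), class = "malaise_truth")
}

#' Generate synthetic weather-station series with known components
#'
#' Builds station-day values as annual trend + cyclic seasonal sinusoid +
#' altitude effect + spatially structured or white noise — the forward model
#' of the station decomposition, for recovery tests and demos.
#'
#' @param n_stations Number of stations.
#' @param years Calendar years.
#' @param seed Integer seed; required.
#' @param trend_per_year Linear trend in value units per year.
#' @param seasonal_amp Amplitude of the seasonal sinusoid.
#' @param altitude_coef Value units per meter of altitude.
#' @param noise_sd Station-day noise sd.
#' @param spatial_range_km If positive, noise is drawn per day from a
#'   spatially correlated exponential-covariance field with this range.
#' @param mean_level Overall mean level.
#' @param doys Day-of-year grid (default every 4th day, keeping series small).
#' @return List: `stations` tibble, `series` tibble
#'   (`station_id, lon, lat, alt_m, year, doy, value`), and `truth`.
#' @export
generate_station_series <- function(n_stations, years, seed,
                                    trend_per_year = 0.05, seasonal_amp = 8,
                                    altitude_coef = -0.006, noise_sd = 1,
                                    spatial_range_km = 0, mean_level = 10,
                                    doys = seq(0L, 364L, by = 4L)) {
  if (missing(seed) || is.null(seed)) abort("generate_station_series requires `seed`")
  set.seed(seed)
  stations <- tibble::tibble(
    station_id = sprintf("W%03d", seq_len(n_stations)),
    lon = runif(n_stations, 6.0, 8.0),
    lat = runif(n_stations, 50.5, 52.0),
    alt_m = runif(n_stations, 20, 400)
  )
  grid <- tidyr::expand_grid(station_id = stations$station_id,
                             year = as.integer(years), doy = as.integer(doys))
  grid <- dplyr::left_join(grid, stations, by = "station_id")
  det <- mean_level + trend_per_year * (grid$year - min(years)) +
    seasonal_amp * cos(2 * pi * (grid$doy - 196) / 365) +
    altitude_coef * grid$alt_m
  noise <- if (spatial_range_km > 0) {
    D <- geosphere::distm(as.matrix(stations[, c("lon", "lat")]),
                          fun = geosphere::distHaversine) / 1000
    L <- chol(exp(-D / spatial_range_km) + diag(1e-8, n_stations))
    keyed <- split(seq_len(nrow(grid)), paste(grid$year, grid$doy))
    out <- numeric(nrow(grid))
    for (ix in keyed) {
      f <- noise_sd * drop(rnorm(n_stations) %*% L)
      out[ix] <- f[match(grid$station_id[ix], stations$station_id)]
    }
    out
  } else {
    rnorm(nrow(grid), 0, noise_sd)
  }
  series <- dplyr::mutate(grid, value = det + noise)
  list(stations = stations, series = series,
       truth = list(trend_per_year = trend_per_year, seasonal_amp = seasonal_amp,
                    altitude_coef = altitude_coef, noise_sd = noise_sd,
                    spatial_range_km = spatial_range_km, mean_level = mean_level))
}
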