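#' Decompose station weather series into trend, season, anomaly and altitude
#'
#' Fits `value = f_k(year) + f_t(doy) + a * altitude + r(year, doy) +
#' residual`: a thin-plate penalized spline over years (long-term trend), a
#' cyclic cubic penalized spline over day-of-year (mean seasonal profile,
#' periodic over the 365-day cycle), a linear altitude effect, and per-year
#' smooths of the daily station-mean residuals (the annual seasonal
#' anomaly).  Smoothing penalties are selected by generalized
#' cross-validation.  The reconstruction identity `f_k + f_t + a*h + r +
#' residual = value` holds at every station-day by construction.
#'
#' @param series Tibble with columns
#'   `station_id, lon, lat, alt_m, year, doy, value` (one weather variable).
#' @param k_annual,k_seasonal Basis dimensions of the annual and seasonal
#'   smooths (reduced automatically for short series).
#' @return A `weather_decomposition` object: tibbles `f_k` (per year),
#'   `f_t` (per day-of-year), `r` (year × day), `altitude_coef` with
#'   standard error, and per-station-day `residuals`.
#' @export
decompose_weather <- function(series, k_annual = 10, k_seasonal = 20) {
  check_columns(series, c("station_id", "lon", "lat", "alt_m", "year", "doy", "value"),
                "station series")
  if (dplyr::n_distinct(series$station_id) < 2) {
    abort("need >= 2 stations: the altitude coefficient is unidentifiable from one")
  }
  years <- sort(unique(series$year))
  if (length(years) < 2) abort("need >= 2 years")
  df <- dplyr::arrange(tibble::as_tibble(series), .data$station_id, .data$year,
                       .data$doy)

  ky <- min(k_annual, length(years) - 1L)
  ks <- min(k_seasonal, max(4L, dplyr::n_distinct(df$doy) - 1L))
  use_spline_year <- length(years) >= 4
  form <- if (use_spline_year) {
    value ~ s(year, bs = "tp", k = ky) + s(doy, bs = "cc", k = ks) + alt_m
  } else {
    value ~ year + s(doy, bs = "cc", k = ks) + alt_m
  }
  fit <- mgcv::gam(form, data = df, knots = list(doy = c(0, 365)), method = "GCV.Cp")

  terms <- predict(fit, type = "terms")
  icpt <- unname(coef(fit)["(Intercept)"])
  year_col <- grep("year", colnames(terms), value = TRUE)[1]
  doy_col <- grep("doy", colnames(terms), value = TRUE)[1]
  a <- unname(coef(fit)["alt_m"])
  a_se <- sqrt(diag(stats::vcov(fit)))[["alt_m"]]

  f_k <- tibble::tibble(year = df$year, value = icpt + terms[, year_col]) |>
    dplyr::distinct(.data$year, .keep_all = TRUE) |>
    dplyr::arrange(.data$year)
  f_t <- tibble::tibble(doy = df$doy, value = terms[, doy_col]) |>
    dplyr::distinct(.data$doy, .keep_all = TRUE) |>
    dplyr::arrange(.data$doy)

  resid1 <- df$value - unname(predict(fit, newdata = df))

  # annual anomaly: smooth of daily station-mean residuals, one per year
  mean_res <- tibble::tibble(year = df$year, doy = df$doy, resid = resid1) |>
    dplyr::summarise(m = mean(.data$resid), .by = c("year", "doy"))
  r_fits <- lapply(split(mean_res, mean_res$year), function(d) {
    if (nrow(d) >= 6) {
      mgcv::gam(m ~ s(doy, k = min(10, nrow(d) - 1)), data = d, method = "GCV.Cp")
    } else {
      structure(list(const = mean(d$m)), class = "const_smooth")
    }
  })
  predict_r <- function(year, doy) {
    out <- numeric(length(year))
    for (y in unique(year)) {
      ix <- year == y
      f <- r_fits[[as.character(y)]]
      out[ix] <- if (is.null(f)) 0
      else if (inherits(f, "const_smooth")) f$const
      else unname(predict(f, newdata = data.frame(doy = doy[ix])))
    }
    out
  }
  r_val <- predict_r(df$year, df$doy)
  r_tab <- mean_res |>
    dplyr::mutate(value = predict_r(.data$year, .data$doy)) |>
    dplyr::select("year", "doy", "value")

  residuals <- tibble::tibble(
    station_id = df$station_id, lon = df$lon, lat = df$lat, alt_m = df$alt_m,
    year = df$year, doy = df$doy, resid = resid1 - r_val
  )

  structure(list(
    f_k = f_k, f_t = f_t, r = r_tab,
    altitude_coef = a, altitude_se = a_se,
    residuals = residuals,
    gam = fit, r_fits = r_fits, predict_r = predict_r,
    station_bbox = c(lon = range(df$lon), lat = range(df$lat)),
    years = years
  ), class = "weather_decomposition")
}

#' @export
print.weather_decomposition <- function(x, ...) {
  cat("<weather_decomposition>", length(x$years), "years,",
      dplyr::n_distinct(x$residuals$station_id), "stations; altitude coef",
      format(x$altitude_coef, digits = 3), "per m\n")
  invisible(x)
}

# deterministic part (trend + season + anomaly + altitude) at a location
predict_deterministic <- function(decomp, year, doy, alt_m) {
  base <- as.numeric(predict(decomp$gam,
                             newdata = data.frame(year = year, doy = doy,
                                                  alt_m = alt_m)))
  base + decomp$predict_r(year, doy)
}

# great-circle distance matrix in km (haversine, consistently everywhere)
haversine_km <- function(x, y = NULL) {
  if (is.null(y)) {
    geosphere::distm(x, fun = geosphere::distHaversine) / 1000
  } else {
    geosphere::distHaversine(x, y) / 1000
  }
}

#' Fit a separable exponential space-time covariance to station residuals
#'
#' Computes an empirical spatio-temporal semivariogram from (sampled) pairs
#' of residuals binned by great-circle distance and day lag, then fits
#' `gamma(h, u) = nugget + psill * (1 - exp(-h/rs - u/rt))` by weighted
#' least squares (weights proportional to bin pair counts).
#'
#' @param residuals The `residuals` tibble of a [decompose_weather()] (or
#'   any tibble with `lon, lat, year, doy, resid`).
#' @param max_pairs Maximum number of random residual pairs to evaluate.
#' @param n_space_bins Number of spatial-lag bins.
#' @param max_time_lag Largest day lag considered.
#' @param seed Seed for pair subsampling (default 1; the estimator is a
#'   binned method-of-moments fit, so this only affects Monte-Carlo noise).
#' @return A `covariance_model`: `spatial_range_km`, `temporal_range_days`,
#'   `sill`, `nugget`, `degenerate` flag and the binned empirical
#'   variogram.
#' @export
fit_covariance <- function(residuals, max_pairs = 2e5, n_space_bins = 8,
                           max_time_lag = 5, seed = 1) {
  check_columns(residuals, c("lon", "lat", "year", "doy", "resid"), "residuals")
  n <- nrow(residuals)
  if (n < 30) abort("need >= 30 station-day residuals")
  if (all(abs(residuals$resid) < 1e-12)) {
    warn("all residuals are zero; returning degenerate covariance model")
    return(structure(list(spatial_range_km = 0, temporal_range_days = 0,
                          sill = 0, nugget = 0, degenerate = TRUE,
                          empirical = tibble::tibble()),
                     class = "covariance_model"))
  }
  set.seed(seed)
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n, max_pairs, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  tday <- residuals$year * 365L + residuals$doy
  u <- abs(tday[i] - tday[j])
  keep <- u <= max_time_lag
  i <- i[keep]; j <- j[keep]; u <- u[keep]
  if (length(i) < 100) abort("too few close-in-time residual pairs")
  h <- haversine_km(cbind(residuals$lon[i], residuals$lat[i]),
                    cbind(residuals$lon[j], residuals$lat[j]))
  sq <- (residuals$resid[i] - residuals$resid[j])^2

  h_breaks <- c(-1e-9, seq(1e-3, max(h) + 1e-6, length.out = n_space_bins))
  hb <- cut(h, h_breaks, labels = FALSE)
  emp <- tibble::tibble(hb = hb, u = u, h = h, sq = sq) |>
    dplyr::summarise(h = mean(.data$h), gamma = mean(.data$sq) / 2,
                     n = dplyr::n(), .by = c("hb", "u")) |>
    dplyr::filter(.data$n >= 10)

  v_tot <- var(residuals$resid)
  obj <- function(par) {
    nug <- exp(par[1]); ps <- exp(par[2]); rs <- exp(par[3]); rt <- exp(par[4])
    g <- nug + ps * (1 - exp(-emp$h / rs - emp$u / rt))
    sum(emp$n * (emp$gamma - g)^2)
  }
  start <- log(c(max(v_tot / 2, 1e-6), max(v_tot / 2, 1e-6), 30, 2))
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  nug <- exp(opt$par[1]); ps <- exp(opt$par[2])
  structure(list(
    spatial_range_km = exp(opt$par[3]),
    temporal_range_days = exp(opt$par[4]),
    sill = nug + ps, nugget = nug, psill = ps,
    degenerate = FALSE, empirical = emp, converged = opt$convergence == 0
  ), class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> sill %.3g (nugget %.3g), ranges %.1f km / %.1f d%s\n",
              x$sill, x$nugget, x$spatial_range_km, x$temporal_range_days,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Interpolate daily weather values to a trap location by kriging
#'
#' Prediction = deterministic components (trend, season, anomaly, altitude)
#' evaluated at the target plus the ordinary-kriging interpolation of the
#' same-day station residuals under the fitted spatial covariance.  With a
#' zero nugget the interpolator is exact at station locations.  Stations
#' farther than `max_km` (default 100 km) are excluded; a day with no
#' station inside the radius is an error.
#'
#' @param decomp A [decompose_weather()] result.
#' @param model A [fit_covariance()] result.
#' @param target List or one-row data frame with `lon`, `lat`, `alt_m`.
#' @param dates Tibble with columns `year`, `doy`.
#' @param max_km Station-inclusion radius in km.
#' @return Tibble `year, doy, value`.
#' @export
krige_daily <- function(decomp, model, target, dates, max_km = 100) {
  stopifnot(inherits(decomp, "weather_decomposition"),
            inherits(model, "covariance_model"))
  target <- as.list(target)
  check_columns(dates, c("year", "doy"), "dates")
  bb <- decomp$station_bbox
  if (target$lon < bb["lon1"] || target$lon > bb["lon2"] ||
      target$lat < bb["lat1"] || target$lat > bb["lat2"]) {
    warn("target lies outside the stations' bounding region")
  }
  res <- decomp$residuals
  cov_fun <- function(h) {
    if (isTRUE(model$degenerate) || model$sill == 0) return(rep(0, length(h)))
    (model$sill - model$nugget) * exp(-h / model$spatial_range_km) +
      model$nugget * (h < 1e-9)
  }
  out <- purrr::pmap_dfr(dates, function(year, doy) {
    day <- res[res$year == year & res$doy == doy, ]
    if (nrow(day) == 0) abort(sprintf("no station residuals for year %d day %d",
                                      year, doy))
    h0 <- haversine_km(cbind(day$lon, day$lat), c(target$lon, target$lat))
    day <- day[h0 <= max_km, ]
    h0 <- h0[h0 <= max_km]
    if (nrow(day) == 0) {
      abort(sprintf("no weather station within %g km for year %d day %d",
                    max_km, year, doy))
    }
    k <- nrow(day)
    r_hat <- if (isTRUE(model$degenerate) || model$sill == 0) {
      mean(day$resid)
    } else {
      H <- haversine_km(as.matrix(day[, c("lon", "lat")]))
      C <- cov_fun(H)
      A <- rbind(cbind(C, 1), c(rep(1, k), 0))
      b <- c(cov_fun(h0), 1)
      wl <- tryCatch(solve(A, b),
                     error = function(e) solve(A + diag(1e-8, k + 1), b))
      sum(wl[seq_len(k)] * day$resid)
    }
    det <- predict_deterministic(decomp, year, doy, target$alt_m)
    tibble::tibble(year = year, doy = doy, value = as.numeric(det + r_hat))
  })
  out
}

# values of a winter window (1 Nov of year-1 through 28 Feb of year),
# checking completeness
winter_values <- function(series, year, window = c(DOY_NOV1, DOY_FEB28)) {
  check_columns(series, c("year", "doy", "value"), "series")
  need <- rbind(
    data.frame(year = year - 1L, doy = seq(window[1], 364L)),
    data.frame(year = year, doy = seq(0L, window[2]))
  )
  idx <- match(paste(need$year, need$doy), paste(series$year, series$doy))
  if (anyNA(idx)) {
    miss <- need[is.na(idx), ]
    abort(sprintf("missing %d winter day(s), first gaps: %s", sum(is.na(idx)),
                  paste(sprintf("%d/day%d", miss$year, miss$doy)[seq_len(min(5, nrow(miss)))],
                        collapse = ", ")))
  }
  series$value[idx]
}

#' Number of frost days in the preceding winter
#'
#' Counts days with daily mean temperature strictly below 0 °C in the
#' November-February window preceding the sampling season of `year`
#' (1 November of `year - 1` through 28 February of `year`).
#'
#' @param series Daily temperature tibble (`year, doy, value`), °C.
#' @param year Sampling-season calendar year.
#' @param window Day-of-year endpoints of the winter window (start in the
#'   preceding year, end in `year`).
#' @return Integer count of frost days.
#' @export
frost_days <- function(series, year, window = c(DOY_NOV1, DOY_FEB28)) {
  sum(winter_values(series, year, window) < 0)
}

#' Winter precipitation sum preceding a sampling season
#'
#' @param series Daily precipitation tibble (`year, doy, value`), mm.
#' @inheritParams frost_days
#' @return Precipitation sum in mm.
#' @export
winter_precip <- function(series, year, window = c(DOY_NOV1, DOY_FEB28)) {
  sum(winter_values(series, year, window))
}
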