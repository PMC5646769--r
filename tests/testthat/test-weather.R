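test_that("a constant field decomposes into constants with zero residuals", {
  grid <- tidyr::expand_grid(station_id = c("w1", "w2", "w3"),
                             year = 2000:2003, doy = seq(0L, 360L, by = 8L))
  st <- tibble::tibble(station_id = c("w1", "w2", "w3"),
                       lon = c(6, 6.5, 7), lat = c(51, 51.3, 51.6),
                       alt_m = c(50, 50, 50))
  series <- dplyr::left_join(grid, st, by = "station_id") |>
    dplyr::mutate(value = 9.5)
  dec <- decompose_weather(series)
  expect_lt(diff(range(dec$f_k$value)), 1e-6)
  expect_lt(diff(range(dec$f_t$value)), 1e-6)
  expect_lt(max(abs(dec$residuals$resid)), 1e-6)
  expect_error(decompose_weather(series[series$station_id == "w1", ]),
               "2 stations")
})

test_that("altitude and seasonal components are recovered from simulated stations", {
  g <- generate_station_series(25, 2000:2005, seed = 10, trend_per_year = 0.08,
                               seasonal_amp = 8, altitude_coef = 0.006,
                               noise_sd = 0.6)
  dec <- decompose_weather(g$series)
  expect_lt(abs(dec$altitude_coef - 0.006), 2 * dec$altitude_se)
  truth_season <- 8 * cos(2 * pi * (dec$f_t$doy - 196) / 365)
  expect_gt(cor(dec$f_t$value, truth_season), 0.99)
  # annual smooth tracks the linear trend
  expect_gt(cor(dec$f_k$value, dec$f_k$year), 0.95)
})

test_that("decomposition reconstructs every station-day exactly", {
  g <- generate_station_series(12, 2001:2004, seed = 11, noise_sd = 1.2)
  dec <- decompose_weather(g$series)
  df <- dec$residuals
  fk <- setNames(dec$f_k$value, dec$f_k$year)
  ft <- setNames(dec$f_t$value, dec$f_t$doy)
  rr <- setNames(dec$r$value, paste(dec$r$year, dec$r$doy))
  recon <- fk[as.character(df$year)] + ft[as.character(df$doy)] +
    rr[paste(df$year, df$doy)] + dec$altitude_coef * df$alt_m + df$resid
  obs <- dplyr::arrange(g$series, station_id, year, doy)$value
  expect_lt(max(abs(recon - obs)), 1e-6 * sd(obs))
  expect_lt(abs(mean(df$resid)), 0.05 * sd(obs))
})

test_that("variogram fitting separates structure from nugget", {
  # white noise: almost everything in the nugget at short range
  set.seed(5)
  st <- tibble::tibble(lon = runif(40, 6, 8), lat = runif(40, 50.5, 52))
  res <- tidyr::expand_grid(i = 1:40, year = 2000L, doy = 0:24) |>
    dplyr::mutate(lon = st$lon[i], lat = st$lat[i], resid = rnorm(dplyr::n()),
                  station_id = sprintf("w%02d", i))
  cm <- fit_covariance(res)
  struct_at_10km <- (cm$sill - cm$nugget) *
    exp(-10 / cm$spatial_range_km - 1 / cm$temporal_range_days)
  expect_lt(struct_at_10km, 0.2 * cm$sill)

  # spatially correlated field: range and sill recovered
  g <- generate_station_series(100, 2000:2001, seed = 12, trend_per_year = 0,
                               seasonal_amp = 0, altitude_coef = 0,
                               noise_sd = 1, spatial_range_km = 50,
                               doys = seq(0L, 120L, by = 8L))
  res2 <- dplyr::transmute(g$series, station_id, lon, lat, year, doy,
                           resid = value - mean(value))
  cm2 <- fit_covariance(res2)
  expect_lt(abs(cm2$spatial_range_km - 50) / 50, 0.5)
  expect_lt(abs(cm2$sill - 1) / 1, 0.35)

  zero <- dplyr::mutate(res2, resid = 0)
  expect_warning(cm0 <- fit_covariance(zero), "degenerate")
  expect_equal(cm0$sill, 0)
  expect_error(fit_covariance(res2[1:10, ]), "30")
})

test_that("kriging is exact at stations with zero nugget and respects the radius", {
  g <- generate_station_series(10, 2000:2002, seed = 13, noise_sd = 1,
                               spatial_range_km = 60)
  dec <- decompose_weather(g$series)
  model <- structure(list(spatial_range_km = 60, temporal_range_days = 2,
                          sill = 1, nugget = 0, degenerate = FALSE),
                     class = "covariance_model")
  st1 <- g$stations[1, ]
  obs <- dplyr::filter(g$series, station_id == st1$station_id,
                       year == 2001, doy == 100)
  pred <- krige_daily(dec, model,
                      list(lon = st1$lon, lat = st1$lat, alt_m = st1$alt_m),
                      tibble::tibble(year = 2001L, doy = 100L))
  expect_equal(pred$value, obs$value, tolerance = 1e-6)

  # far target: no station within 100 km
  expect_error(
    krige_daily(dec, model, list(lon = 20, lat = 40, alt_m = 50),
                tibble::tibble(year = 2001L, doy = 100L)) |>
      suppressWarnings(),
    "within 100")
})

test_that("a constant field is interpolated to its constant anywhere", {
  grid <- tidyr::expand_grid(station_id = c("w1", "w2"), year = 2000:2001,
                             doy = seq(0L, 360L, by = 10L))
  st <- tibble::tibble(station_id = c("w1", "w2"), lon = c(6.4, 6.8),
                       lat = c(51, 51), alt_m = c(50, 50))
  series <- dplyr::left_join(grid, st, by = "station_id") |>
    dplyr::mutate(value = 3.25)
  dec <- decompose_weather(series)
  model <- structure(list(spatial_range_km = 40, temporal_range_days = 2,
                          sill = 1, nugget = 0, degenerate = FALSE),
                     class = "covariance_model")
  midway <- krige_daily(dec, model, list(lon = 6.6, lat = 51, alt_m = 50),
                        tibble::tibble(year = 2000L, doy = 100L))
  expect_equal(midway$value, 3.25, tolerance = 1e-6)
})

test_that("kriging beats nearest-neighbour interpolation on a smooth field", {
  g <- generate_station_series(30, 2000:2001, seed = 14, trend_per_year = 0,
                               seasonal_amp = 4, altitude_coef = 0,
                               noise_sd = 1, spatial_range_km = 120,
                               doys = seq(50L, 120L, by = 10L))
  err_k <- c(); err_nn <- c()
  for (hold in g$stations$station_id[1:5]) {
    train <- dplyr::filter(g$series, station_id != hold)
    test <- dplyr::filter(g$series, station_id == hold, doy == 80)
    dec <- decompose_weather(train)
    cm <- fit_covariance(dec$residuals)
    tgt <- g$stations[g$stations$station_id == hold, ]
    # a held-out station can sit on the hull of the remaining network, so
    # the outside-bounding-region warning is expected here
    pred <- suppressWarnings(
      krige_daily(dec, cm, list(lon = tgt$lon, lat = tgt$lat,
                                alt_m = tgt$alt_m),
                  dplyr::select(test, year, doy)))
    err_k <- c(err_k, pred$value - test$value)
    day_obs <- dplyr::filter(train, doy == 80)
    nn <- day_obs |>
      dplyr::mutate(d = geosphere::distHaversine(cbind(lon, lat),
                                                 c(tgt$lon, tgt$lat))) |>
      dplyr::slice_min(d, n = 1, by = year) |>
      dplyr::arrange(year)
    err_nn <- c(err_nn, nn$value - dplyr::arrange(test, year)$value)
  }
  expect_lt(sqrt(mean(err_k^2)), sqrt(mean(err_nn^2)))
})

test_that("frost days and winter precipitation equal brute-force window loops", {
  days <- rbind(data.frame(year = 2000L, doy = 304:364),
                data.frame(year = 2001L, doy = 0:58))
  warm <- tibble::tibble(year = days$year, doy = days$doy, value = 5)
  expect_equal(frost_days(warm, 2001L), 0L)

  set.seed(8)
  temp <- tibble::tibble(year = days$year, doy = days$doy,
                         value = runif(nrow(days), 0.5, 8))
  temp$value[sample(nrow(temp), 17)] <- -runif(17, 0.1, 5)
  expect_equal(frost_days(temp, 2001L), 17L)

  zero_boundary <- dplyr::mutate(warm, value = 0)
  expect_equal(frost_days(zero_boundary, 2001L), 0L) # 0 degC is not frost

  gaps <- temp[-(3:5), ]
  expect_error(frost_days(gaps, 2001L), "missing 3 winter day")

  precip0 <- dplyr::mutate(warm, value = 0)
  expect_equal(winter_precip(precip0, 2001L), 0)
  precip1 <- dplyr::mutate(warm, value = 1)
  expect_equal(winter_precip(precip1, 2001L), 120)
  set.seed(9)
  pr <- dplyr::mutate(warm, value = rexp(nrow(warm), 1))
  expect_equal(winter_precip(pr, 2001L), sum(pr$value))
})
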