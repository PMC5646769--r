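#' Build the day-level design matrix for a model specification
#'
#' Expands every catch into its exposure days (inclusive endpoints) and
#' assembles the fixed-effect design: a quadratic seasonal profile in day
#' number, the year index, habitat-cluster dummies, and whatever weather,
#' habitat and land-use columns the specification requires.  Continuous
#' covariates are standardized to mean 0, sd 1 over the day rows of the
#' build set; the year index, cluster dummies and land-use fractions are
#' exempt.  Interaction columns are products of the (post-standardization)
#' components and are not re-standardized.
#'
#' @param samples Samples tibble (see [read_samples()]).
#' @param sites Sites tibble (see [read_sites()]).
#' @param spec A [model_spec()].
#' @param daily Optional day-level covariates: `site_id, year, doy` plus any
#'   of `temperature, precipitation, wind`.
#' @param site_year Optional site-year covariates: `site_id, year` plus any
#'   of `frost_days, winter_precip, herb_richness, tree_richness,
#'   ell_nitrogen, ell_ph, ell_moisture, ell_light, ell_temperature, arable,
#'   grassland, forest, water`.
#' @param year_coding `"calendar"` (default): year index = calendar year −
#'   first year + 1, so gap years keep their spacing; `"consecutive"`:
#'   consecutive integers 1, 2, ... over the sampled years only.
#' @return An object of class `biomass_design` holding the day-level matrix
#'   `X`, per-sample bookkeeping and the standardization record.
#' @export
build_design <- function(samples, sites, spec, daily = NULL, site_year = NULL,
                         year_coding = c("calendar", "consecutive")) {
  year_coding <- match.arg(year_coding)
  samples <- validate_samples(samples)
  sites <- validate_sites(sites)
  stopifnot(inherits(spec, "model_spec"))
  missing_sites <- setdiff(samples$site_id, sites$site_id)
  if (length(missing_sites)) {
    abort(sprintf("samples reference unknown site(s): %s",
                  paste(head(missing_sites, 5), collapse = ", ")))
  }

  year_min <- min(samples$year)
  year_levels <- sort(unique(samples$year))
  code_year <- function(y) {
    if (year_coding == "calendar") as.integer(y - year_min + 1L)
    else match(y, year_levels)
  }

  lens <- samples$tau2 - samples$tau1 + 1L
  day_sample <- rep(seq_len(nrow(samples)), lens)
  raw <- tibble::tibble(
    site_id = samples$site_id[day_sample],
    year = samples$year[day_sample],
    doy = sequence(lens) - 1L + rep(samples$tau1, lens),
    year_code = code_year(samples$year)[day_sample],
    cluster = sites$cluster[match(samples$site_id[day_sample], sites$site_id)]
  )

  cols <- spec_columns(spec)
  need_daily <- intersect(spec$main, DAY_VARYING)
  if (length(need_daily)) {
    if (is.null(daily)) abort(sprintf("spec '%s' needs daily covariates: %s",
                                      spec$name, paste(need_daily, collapse = ", ")))
    check_columns(daily, c("site_id", "year", "doy", need_daily), "daily covariates")
    key <- paste(daily$site_id, daily$year, daily$doy)
    idx <- match(paste(raw$site_id, raw$year, raw$doy), key)
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      abort(sprintf("missing daily covariate for site %s, year %d, day %d",
                    raw$site_id[miss], raw$year[miss], raw$doy[miss]))
    }
    for (cn in need_daily) raw[[cn]] <- daily[[cn]][idx]
  }
  need_sy <- intersect(spec$main, SITE_YEAR_COVARIATES)
  if (length(need_sy)) {
    if (is.null(site_year)) abort(sprintf("spec '%s' needs site-year covariates: %s",
                                          spec$name, paste(need_sy, collapse = ", ")))
    check_columns(site_year, c("site_id", "year", need_sy), "site-year covariates")
    idx <- match(paste(raw$site_id, raw$year), paste(site_year$site_id, site_year$year))
    if (anyNA(idx)) {
      miss <- which(is.na(idx))[1]
      abort(sprintf("missing site-year covariates for site %s, year %d",
                    raw$site_id[miss], raw$year[miss]))
    }
    for (cn in need_sy) raw[[cn]] <- site_year[[cn]][idx]
  }

  built <- make_design_columns(raw, spec, record = NULL)
  built$record$year_coding <- year_coding
  built$record$year_min <- year_min
  built$record$year_levels <- year_levels

  site_levels <- sites$site_id
  ends <- cumsum(lens)
  structure(list(
    X = built$X,
    mass = samples$mass_g,
    samples = samples,
    n_samples = nrow(samples),
    day_sample = day_sample,
    sample_len = lens,
    sample_ends = ends,
    sample_site = match(samples$site_id, site_levels),
    sample_year_code = code_year(samples$year),
    day_site = match(raw$site_id, site_levels),
    site_levels = site_levels,
    record = built$record,
    spec = spec
  ), class = "biomass_design")
}

#' @export
print.biomass_design <- function(x, ...) {
  cat("<biomass_design>", x$n_samples, "samples,", nrow(x$X), "exposure days,",
      ncol(x$X), "design columns (spec:", x$spec$name, ")\n")
  invisible(x)
}

# Build (or re-apply) the design columns from a raw day-level frame with
# columns doy, year_code, cluster and the raw covariates.  `record` NULL
# computes the standardization statistics; otherwise they are reused, which
# is how projection day grids are put on the fitted scale.
make_design_columns <- function(raw, spec, record = NULL) {
  fresh <- is.null(record)
  stats <- if (fresh) list() else record$stats
  std <- function(x, key) {
    if (fresh) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      stats[[key]] <<- c(mean = mean(x), sd = s)
    }
    (x - stats[[key]]["mean"]) / stats[[key]]["sd"]
  }

  n <- nrow(raw)
  vals <- list()
  day_std <- std(raw$doy, "day")
  for (col in spec$main) {
    vals[[col]] <- switch(
      col,
      day = day_std,
      day2 = std(day_std^2, "day2"),
      year = raw$year_code,
      cluster2 = as.numeric(raw$cluster == 2L),
      cluster3 = as.numeric(raw$cluster == 3L),
      {
        if (is.null(raw[[col]])) abort(sprintf("raw covariate '%s' not supplied", col))
        if (col %in% STANDARDIZATION_EXEMPT) as.numeric(raw[[col]])
        else std(as.numeric(raw[[col]]), col)
      }
    )
  }
  for (int in spec$interactions) {
    parts <- strsplit(int, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(vals))) {
      abort(sprintf("interaction '%s' references a column not in the spec", int))
    }
    vals[[int]] <- vals[[parts[1]]] * vals[[parts[2]]]
  }
  X <- do.call(cbind, vals)
  rownames(X) <- NULL
  rec <- if (fresh) {
    structure(list(stats = stats, spec = spec), class = "design_record")
  } else record
  list(X = X, record = rec)
}

#' Design rows for new data on the fitted scale
#'
#' Applies a fitted design's standardization record to a new raw day-level
#' frame — the mechanism behind seasonal projections.
#'
#' @param record A `design_record` (the `record` element of a
#'   [build_design()] result or of a fitted model).
#' @param newdata Tibble with columns `doy`, `year_code`, `cluster`, plus
#'   any raw covariates the spec needs.
#' @return Numeric matrix with the fitted design's columns.
#' @export
design_newdata <- function(record, newdata) {
  needed <- setdiff(record$spec$main,
                    c("day", "day2", "year", "cluster2", "cluster3"))
  check_columns(newdata, c("doy", "year_code", "cluster", needed), "newdata")
  make_design_columns(newdata, record$spec, record = record)$X
}
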