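# Synthetic-world generator: gridded predictors, a virtual station network and
# ground-truth temperature with a known data-generating process, so the whole
# pipeline can be exercised and validated without external data.

#' Configuration of a synthetic world
#'
#' Describes the study-like conditions emulated by [generate_world()]: a
#' 500 m grid, a five-year daily calendar, 48 stations placed mostly in the
#' urban core, and roughly 10% missing station-days. True temperature is a
#' linear combination of the generated predictors plus a smooth spatial field
#' and iid noise, with an optional quadratic term in `t2m` to make the
#' data-generating process non-linear.
#'
#' @param n_rows,n_cols grid size in cells.
#' @param cell_size_m cell edge, metres.
#' @param date_start,date_end daily calendar bounds.
#' @param n_stations number of virtual stations.
#' @param missing_frac_target target fraction of masked station-days in
#'   `[0, 1)`.
#' @param coefficients named numeric vector of effect sizes (degrees C per
#'   unit of each named feature). Every name must be a generated feature.
#' @param intercept degrees C added to the linear predictor.
#' @param nonlinear_coef degrees C per unit of `((t2m - 20) / 5)^2`; 0 (the
#'   default) keeps the generating process linear in the features.
#' @param noise_sd iid station-day noise, degrees C.
#' @param field_sd standard deviation of the smooth spatial residual field,
#'   degrees C.
#' @param spatial_range correlation length of the smooth field, metres.
#' @param urban_core_frac fraction of cells inside the urban disc.
#' @param station_urban_frac fraction of stations placed in urban cells.
#' @param n_decoys number of pure-noise decoy predictors.
#' @param lat_range latitude band mapped onto rows (south first).
#' @param seed master seed; all randomness flows from it through named
#'   substreams.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_rows = 20, n_cols = 20, cell_size_m = 500,
                         date_start = "2015-01-01", date_end = "2019-12-31",
                         n_stations = 48, missing_frac_target = 0.10,
                         coefficients = default_coefficients(),
                         intercept = 2.5, nonlinear_coef = 0,
                         noise_sd = 0.5, field_sd = 0.3,
                         spatial_range = 2000,
                         urban_core_frac = 0.25, station_urban_frac = 0.8,
                         n_decoys = 3,
                         lat_range = c(-24.1, -23.3), seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_stations >= 1,
            missing_frac_target >= 0, missing_frac_target < 1,
            noise_sd >= 0, field_sd >= 0, n_decoys >= 0)
  if (as_date(date_end) < as_date(date_start))
    stop_gridta("date_end must be >= date_start")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_m = cell_size_m,
    date_start = as_date(date_start), date_end = as_date(date_end),
    n_stations = as.integer(n_stations),
    missing_frac_target = missing_frac_target,
    coefficients = coefficients, intercept = intercept,
    nonlinear_coef = nonlinear_coef,
    noise_sd = noise_sd, field_sd = field_sd,
    spatial_range = spatial_range,
    urban_core_frac = urban_core_frac,
    station_urban_frac = station_urban_frac,
    n_decoys = as.integer(n_decoys),
    lat_range = lat_range, seed = as.integer(seed)
  ), class = "world_config")
}

#' Default generating coefficients
#'
#' Effect sizes (degrees C per unit) for the features that truly drive the
#' synthetic temperature. The set mirrors the predictors a trained model is
#' expected to pick up: reanalysis air and dew-point temperature dominate,
#' satellite surface temperature and wind contribute, solar geometry adds a
#' seasonal term. All other generated predictors (and the pure-noise decoys)
#' have zero effect.
#'
#' @return a named numeric vector.
#' @export
default_coefficients <- function() {
  c(t2m = 0.75, lst = 0.12, d2m = 0.06, rh = -0.02,
    u10 = 0.10, v10 = 0.15, sza = -0.02, daylength = 0.10)
}

# stationary AR(1) series with marginal sd `sd`
ar1_series <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - phi^2)
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + rnorm(1, 0, innov_sd)
  x
}

# Gaussian smoothing of a matrix (separable kernel, edge-renormalized)
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  sm1 <- function(x) {  # smooth columns of a matrix
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      rs <- pmin(pmax(seq_len(n) + off, 1L), n)  # reflect-less clamp padding
      out <- out + k[j] * x[rs, , drop = FALSE]
    }
    out / sum(k)
  }
  t(sm1(t(sm1(m))))
}

# broadcast helpers: time profile (nt) and spatial map (nr x nc) into arrays
arr_time <- function(x, nr, nc) array(rep(x, times = nr * nc),
                                      dim = c(length(x), nr, nc))
arr_space <- function(m, nt) array(rep(m, each = nt),
                                   dim = c(nt, nrow(m), ncol(m)))

#' Generate a synthetic world
#'
#' Builds daily predictor stacks with seasonal cycles, a north-south gradient,
#' an urban-heat pattern and realistic cross-correlations; static topography
#' and land-use layers; pure-noise decoys; a virtual station network placed
#' preferentially in the urban core; and ground-truth temperature
#' \deqn{Ta(s,t) = \beta_0 + \sum_f \beta_f x_f(s,t) + \gamma z(s,t)^2 +
#'   u(s) + \epsilon(s,t)}
#' where `u` is a smooth spatial field, `z` a standardized `t2m` term (active
#' only when `nonlinear_coef` is non-zero) and `eps ~ N(0, noise_sd^2)`.
#' Station-day missingness and cloud gaps in optical predictors are injected
#' according to `missing_frac_target` (see [inject_missingness()]).
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_dataset`: a list with `predictors`
#'   (named `raster_stack`s), `stations` (one row per station), `obs` (long
#'   station-day table with `ta_true` and `ta_obs`), `truth` (coefficients,
#'   smooth field, noise and missingness mask, plus the noise-free `ta_true`
#'   grid stack), `grid`, `calendar` and `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  grid <- grid_definition(config$n_rows, config$n_cols, config$cell_size_m,
                          lat_range = config$lat_range)
  calendar <- daily_calendar(config$date_start, config$date_end)
  nt <- length(calendar); nr <- grid$n_rows; nc <- grid$n_cols
  doy <- as.integer(format(calendar, "%j"))
  seed <- config$seed

  # urban core: disc around the grid centre covering ~urban_core_frac cells
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dcentre <- sqrt((rows - (nr + 1) / 2)^2 + (cols - (nc + 1) / 2)^2)
  r_urb <- sqrt(config$urban_core_frac * nr * nc / pi)
  urban <- dcentre <= r_urb
  urbw <- exp(-0.5 * (dcentre / r_urb)^2)  # smooth urban-heat weight

  # smooth residual field
  field <- with_stream(seed, "field", {
    f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc),
                         config$spatial_range / grid$cell_size)
    if (sd(f) > 0) f <- f / sd(f)
    f * config$field_sd
  })

  # solar geometry from the row -> latitude map (deterministic)
  lat_rows <- row_latitude(grid, seq_len(nr))
  dl_mat <- vapply(lat_rows, function(l) day_length(l, calendar),
                   numeric(nt))
  sza_mat <- vapply(lat_rows, function(l) solar_zenith_noon(l, calendar),
                    numeric(nt))
  expand_rowfield <- function(m) {  # nt x nr -> (nt, nr, nc)
    array(rep(as.vector(m), times = nc), dim = c(nt, nr, nc))
  }
  daylength_a <- expand_rowfield(dl_mat)
  sza_a <- expand_rowfield(sza_mat)

  # weather: seasonal sinusoid (austral summer peak early Feb) + N-S gradient
  # + urban bump + shared AR(1) day-to-day anomaly + small cell noise
  season <- 20.3 + 3.5 * cos(2 * pi * (doy - 35) / 365.25)
  north_frac <- (nr - rows + 0.5) / nr  # 0 at south edge, 1 at north
  grad_map <- 1.5 * (north_frac - 0.5)
  w <- with_stream(seed, "weather", list(
    anom = ar1_series(nt, 0.8, 2.0),
    t2m_cell = array(rnorm(nt * nr * nc, 0, 0.2), c(nt, nr, nc)),
    dep_anom = ar1_series(nt, 0.6, 0.8),
    dep_cell = array(abs(rnorm(nt * nr * nc, 0, 0.3)), c(nt, nr, nc)),
    u10 = ar1_series(nt, 0.7, 1.5),
    v10 = ar1_series(nt, 0.7, 1.5),
    u10_cell = array(rnorm(nt * nr * nc, 0, 0.3), c(nt, nr, nc)),
    v10_cell = array(rnorm(nt * nr * nc, 0, 0.3), c(nt, nr, nc)),
    sp_anom = ar1_series(nt, 0.8, 300),
    skt_noise = array(rnorm(nt * nr * nc, 0, 0.4), c(nt, nr, nc))
  ))
  t2m_a <- arr_time(season + w$anom, nr, nc) +
    arr_space(grad_map + 1.0 * urbw, nt) + w$t2m_cell
  dep <- pmax(arr_time(3 + 1.5 * cos(2 * pi * (doy - 120) / 365.25) +
                         w$dep_anom, nr, nc) + w$dep_cell, 0.3)
  d2m_a <- t2m_a - dep
  rh_a <- relative_humidity(t2m_a, d2m_a)

  lst_a <- with_stream(seed, "lst", {
    het <- 0.8 + 0.08 * abs(t2m_a - 20)
    t2m_a + arr_space(2.5 * urbw, nt) +
      array(rnorm(nt * nr * nc), c(nt, nr, nc)) * het
  })
  skt_a <- t2m_a + arr_space(0.5 * urbw, nt) + w$skt_noise
  u10_a <- arr_time(w$u10, nr, nc) + w$u10_cell
  v10_a <- arr_time(w$v10, nr, nc) + w$v10_cell

  # topography
  dem_map <- with_stream(seed, "dem", {
    760 + 120 * gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), 2) +
      80 * (1 - north_frac)  # ridge toward the south
  })
  dem <- raster_stack(grid, calendar[1], dem_map, "elevation", "m")
  slope <- slope_from_dem(dem)
  sp_a <- arr_space(101325 - 11.3 * dem_map, nt) + arr_time(w$sp_anom, nr, nc)

  # optical/land-use
  ndvi_a <- with_stream(seed, "ndvi", {
    v <- arr_time(0.08 * cos(2 * pi * (doy - 35) / 365.25), nr, nc) +
      arr_space(0.55 - 0.35 * urbw, nt) +
      array(rnorm(nt * nr * nc, 0, 0.05), c(nt, nr, nc))
    v[] <- pmin(pmax(v, -1), 1)
    v
  })
  bsa_a <- with_stream(seed, "bsa", {
    arr_space(0.15 + 0.08 * urbw, nt) +
      array(rnorm(nt * nr * nc, 0, 0.01), c(nt, nr, nc))
  })

  # lake on a 5x finer mask grid, in the south-west quadrant
  fine <- grid_definition(nr * 5L, nc * 5L, grid$cell_size / 5,
                          grid$origin_x, grid$origin_y,
                          lat_range = grid$lat_range)
  fr <- matrix(seq_len(fine$n_rows), fine$n_rows, fine$n_cols)
  fc <- matrix(seq_len(fine$n_cols), fine$n_rows, fine$n_cols, byrow = TRUE)
  lake_fine <- sqrt((fr - 0.75 * fine$n_rows)^2 +
                    (fc - 0.25 * fine$n_cols)^2) <= 0.12 * fine$n_rows
  lake_mask <- raster_stack(fine, calendar[1], lake_fine + 0, "lake_mask", "")
  lake <- buffer_fraction(lake_mask, grid, grid$cell_size / 10)
  lake$feature_name <- "lake"
  b200m <- buffer_fraction(lake_mask, grid, 200)
  b400m <- buffer_fraction(lake_mask, grid, 400)
  water <- distance_to_feature(grid, lake_mask); water$feature_name <- "water"
  # coastline ~30 km south of the grid: deterministic distance to that line
  ycent <- cell_centre_y(grid, rows)
  coast_map <- (ycent - (grid$origin_y - 30000)) / 1000
  coast <- raster_stack(grid, calendar[1], coast_map, "coast", "km")
  # built environment
  urb_mask <- raster_stack(grid, calendar[1], urban + 0, "urban_mask", "")
  artland <- distance_to_feature(grid, urb_mask)
  artland$feature_name <- "artland"
  popdens_map <- with_stream(seed, "landuse",
    pmax(12000 * urbw + matrix(rnorm(nr * nc, 0, 500), nr, nc), 0))
  impsurf_map <- pmax(pmin(0.85 * urbw +
    with_stream(seed, "impsurf", matrix(rnorm(nr * nc, 0, 0.05), nr, nc)),
    1), 0)
  landcov_map <- ifelse(urban, 1, ifelse(dem_map > stats::median(dem_map), 3, 2))

  st_daily <- function(v, name, units)
    raster_stack(grid, calendar, v, name, units)
  predictors <- list(
    lst = st_daily(lst_a, "lst", "degC"),
    sza = st_daily(sza_a, "sza", "deg"),
    bsa = st_daily(bsa_a, "bsa", "fraction"),
    t2m = st_daily(t2m_a, "t2m", "degC"),
    d2m = st_daily(d2m_a, "d2m", "degC"),
    rh = st_daily(rh_a, "rh", "%"),
    skt = st_daily(skt_a, "skt", "degC"),
    sp = st_daily(sp_a, "sp", "Pa"),
    u10 = st_daily(u10_a, "u10", "m/s"),
    v10 = st_daily(v10_a, "v10", "m/s"),
    elevation = dem, slope = slope,
    ndvi = st_daily(ndvi_a, "ndvi", "index"),
    b200m = b200m, b400m = b400m, lake = lake, water = water, coast = coast,
    popdens = raster_stack(grid, calendar[1], popdens_map, "popdens",
                           "people/km2"),
    impsurf = raster_stack(grid, calendar[1], impsurf_map, "impsurf",
                           "fraction"),
    landcov = raster_stack(grid, calendar[1], landcov_map, "landcov", "class"),
    artland = artland,
    daylength = st_daily(daylength_a, "daylength", "h")
  )
  if (config$n_decoys > 0) {
    decoys <- with_stream(seed, "decoys", {
      lapply(seq_len(config$n_decoys), function(i)
        st_daily(array(rnorm(nt * nr * nc), c(nt, nr, nc)),
                 paste0("noise", i), ""))
    })
    names(decoys) <- paste0("noise", seq_len(config$n_decoys))
    predictors <- c(predictors, decoys)
  }

  beta <- config$coefficients
  missing_feats <- setdiff(names(beta), names(predictors))
  if (length(missing_feats) > 0)
    stop_gridta("coefficients name features not generated: ",
                paste(missing_feats, collapse = ", "))

  # noise-free ground-truth grid stack
  lin <- array(config$intercept, c(nt, nr, nc))
  for (f in names(beta)) {
    pv <- predictors[[f]]$values
    if (is_static(predictors[[f]])) pv <- arr_space(matrix(pv, nr, nc), nt)
    lin <- lin + beta[[f]] * pv
  }
  if (config$nonlinear_coef != 0)
    lin <- lin + config$nonlinear_coef * ((t2m_a - 20) / 5)^2
  ta_true_a <- lin + arr_space(field, nt)
  ta_true <- st_daily(ta_true_a, "ta_true", "degC")

  # stations: mostly in the urban core, minority rural, jittered in-cell
  stations <- with_stream(seed, "stations", {
    n_urb <- round_half_up(config$station_urban_frac * config$n_stations)
    n_rur <- config$n_stations - n_urb
    urb_cells <- which(urban); rur_cells <- which(!urban)
    # dense networks may co-locate several stations in one cell
    pick <- c(sample(urb_cells, n_urb, replace = n_urb > length(urb_cells)),
              sample(rur_cells, n_rur, replace = n_rur > length(rur_cells)))
    row_i <- as.integer((pick - 1) %% nr + 1)
    col_i <- as.integer((pick - 1) %/% nr + 1)
    jx <- runif(length(pick), -0.3, 0.3); jy <- runif(length(pick), -0.3, 0.3)
    data.frame(
      station_id = sprintf("st%02d", seq_along(pick)),
      row = row_i, col = col_i,
      x = cell_centre_x(grid, col_i) + jx * grid$cell_size,
      y = cell_centre_y(grid, row_i) + jy * grid$cell_size,
      urban = urban[cbind(row_i, col_i)]
    )
  })
  stations$lat <- row_latitude(grid, stations$row)

  noise <- with_stream(seed, "noise",
    matrix(rnorm(config$n_stations * nt, 0, config$noise_sd),
           config$n_stations, nt))
  ta_true_st <- t(vapply(seq_len(config$n_stations), function(i)
    ta_true_a[, stations$row[i], stations$col[i]], numeric(nt)))
  obs <- data.frame(
    station_id = rep(stations$station_id, each = nt),
    date = rep(calendar, times = config$n_stations),
    urban = rep(stations$urban, each = nt),
    ta_true = as.vector(t(ta_true_st)),
    ta_obs = as.vector(t(ta_true_st + noise))
  )

  dataset <- structure(list(
    predictors = predictors, stations = stations, obs = obs,
    truth = list(coefficients = beta, intercept = config$intercept,
                 nonlinear_coef = config$nonlinear_coef,
                 field = field, noise = noise, ta_true = ta_true,
                 missing_mask = matrix(FALSE, config$n_stations, nt)),
    grid = grid, calendar = calendar, config = config
  ), class = "synthetic_dataset")

  if (config$missing_frac_target > 0)
    dataset <- inject_missingness(dataset, config)
  dataset
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_dataset> %d x %d grid, %d days (%s..%s), %d stations\n",
    "  %d predictors; observed missing fraction %.3f\n"),
    x$grid$n_rows, x$grid$n_cols, length(x$calendar),
    format(min(x$calendar)), format(max(x$calendar)), nrow(x$stations),
    length(x$predictors), mean(is.na(x$obs$ta_obs))))
  invisible(x)
}

#' Inject missingness into a synthetic dataset
#'
#' Masks station-days as a mixture of station outage blocks and isolated
#' random days until exactly `round(missing_frac_target * N)` slots are
#' masked, and punches cloud-style contiguous spatial blobs into the optical
#' predictors (`lst`, `ndvi`) only. The station-day mask is recorded in
#' `truth$missing_mask`. The real study reports only the overall missing
#' fraction; the block-plus-random mixture is a plausible stand-in mechanism,
#' not an inference about the real networks.
#'
#' @param dataset a `synthetic_dataset`.
#' @param config the [world_config()]; its `missing_frac_target` and `seed`
#'   are used.
#' @return the dataset with `obs$ta_obs` masked and optical gaps applied.
#' @export
inject_missingness <- function(dataset, config = dataset$config) {
  f <- config$missing_frac_target
  if (f >= 1) stop_gridta("missing fraction must be < 1")
  n_st <- nrow(dataset$stations); nt <- length(dataset$calendar)
  mask <- matrix(FALSE, n_st, nt)
  if (f > 0) {
    target <- round_half_up(f * n_st * nt)
    mask <- with_stream(config$seed, "missingness", {
      m <- matrix(FALSE, n_st, nt)
      # outage blocks for roughly half the budget
      while (sum(m) < target / 2) {
        s <- sample.int(n_st, 1)
        len <- min(stats::rgeom(1, 1 / 15) + 5, nt)
        start <- sample.int(max(nt - len + 1, 1), 1)
        m[s, start:(start + len - 1)] <- TRUE
      }
      # isolated random days for the remainder, to the exact count
      open <- which(!m)
      need <- target - sum(m)
      if (need > 0) m[sample(open, min(need, length(open)))] <- TRUE
      if (sum(m) > target) {  # block overshoot: unmask random masked slots
        drop <- sample(which(m), sum(m) - target)
        m[drop] <- FALSE
      }
      m
    })
    idx <- cbind(match(dataset$obs$station_id, dataset$stations$station_id),
                 match(dataset$obs$date, dataset$calendar))
    dataset$obs$ta_obs[mask[idx]] <- NA_real_
  }
  dataset$truth$missing_mask <- mask

  # cloud blobs on optical predictors only
  dataset$predictors[c("lst", "ndvi")] <-
    with_stream(config$seed, "clouds", {
      lapply(dataset$predictors[c("lst", "ndvi")], function(stk) {
        nr <- stk$grid$n_rows; nc <- stk$grid$n_cols
        n_days <- max(1L, round(0.05 * length(stk$times)))
        days <- sample.int(length(stk$times), n_days)
        for (d in days) {
          cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
          rad <- runif(1, 1.5, 4)
          rows <- matrix(seq_len(nr), nr, nc)
          cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
          blob <- (rows - cr)^2 + (cols - cc)^2 <= rad^2
          sl <- stk$values[d, , ]; sl[blob] <- NA_real_
          stk$values[d, , ] <- sl
        }
        stk
      })
    })
  dataset
}

#' Long station-day table of a synthetic dataset
#'
#' @param dataset a `synthetic_dataset`.
#' @param drop_missing drop masked station-days (missing `ta_obs`)?
#' @return a data frame with `station_id`, `x`, `y`, `urban`, `date`,
#'   `ta_obs` (and `ta_true`), the station-table input expected by
#'   [extract_station_values()].
#' @export
station_table <- function(dataset, drop_missing = FALSE) {
  st <- dataset$stations[, c("station_id", "x", "y")]
  out <- merge(dataset$obs, st, by = "station_id", sort = FALSE)
  out <- out[order(out$station_id, out$date),
             c("station_id", "x", "y", "urban", "date", "ta_true", "ta_obs")]
  rownames(out) <- NULL
  if (drop_missing) out <- out[!is.na(out$ta_obs), ]
  out
}

#' Write a synthetic dataset to a directory
#'
#' Stations and observations as CSV, predictors as long-format CSV stacks
#' with JSON headers, and the truth (coefficients, field, mask) as a JSON
#' sidecar.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param predictors which predictor stacks to write (default: all).
#' @return `dir`, invisibly.
#' @export
write_world <- function(dataset, dir, predictors = names(dataset$predictors)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- station_table(dataset)
  st$date <- format(st$date)
  write.csv(st, file.path(dir, "stations.csv"), row.names = FALSE)
  for (f in predictors)
    write_stack_csv(dataset$predictors[[f]],
                    file.path(dir, paste0(f, ".csv")))
  truth <- list(coefficients = as.list(dataset$truth$coefficients),
                intercept = dataset$truth$intercept,
                nonlinear_coef = dataset$truth$nonlinear_coef,
                field = dataset$truth$field,
                missing_mask = dataset$truth$missing_mask)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
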