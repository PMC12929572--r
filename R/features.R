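# Derivation of secondary predictors and harmonization of heterogeneous
# raster stacks to the common daily analysis grid.

#' The candidate predictor catalog
#'
#' Enumerates the 23 candidate predictors considered by the model, with units,
#' native resolutions, the resampling method used to bring each onto the
#' target grid (bilinear for continuous fields, nearest for categorical or
#' mask-derived layers) and a coarse role classification.
#'
#' @return a data frame with one row per feature.
#' @export
feature_catalog <- function() {
  f <- function(name, units, t_res, s_res, resample, role)
    data.frame(name = name, units = units, native_t_res = t_res,
               native_s_res_m = s_res, resample = resample, role = role)
  rbind(
    f("lst",       "degC",      "daily",   1000, "bilinear", "atmospheric"),
    f("sza",       "deg",       "16-day",  1000, "bilinear", "atmospheric"),
    f("bsa",       "fraction",  "daily",    500, "bilinear", "atmospheric"),
    f("t2m",       "degC",      "daily",   9000, "bilinear", "weather"),
    f("d2m",       "degC",      "daily",   9000, "bilinear", "weather"),
    f("rh",        "%",         "daily",   9000, "bilinear", "weather"),
    f("skt",       "degC",      "daily",   9000, "bilinear", "weather"),
    f("sp",        "Pa",        "daily",   9000, "bilinear", "weather"),
    f("u10",       "m/s",       "daily",   9000, "bilinear", "weather"),
    f("v10",       "m/s",       "daily",   9000, "bilinear", "weather"),
    f("elevation", "m",         "static",   500, "bilinear", "topography"),
    f("slope",     "deg",       "static",   500, "bilinear", "topography"),
    f("ndvi",      "index",     "3-month",  500, "bilinear", "land-use"),
    f("b200m",     "fraction",  "static",   100, "nearest",  "land-use"),
    f("b400m",     "fraction",  "static",   100, "nearest",  "land-use"),
    f("lake",      "fraction",  "static",   100, "nearest",  "land-use"),
    f("water",     "km",        "static",   100, "bilinear", "land-use"),
    f("coast",     "km",        "static",   500, "bilinear", "land-use"),
    f("popdens",   "people/km2","static",  1000, "bilinear", "land-use"),
    f("impsurf",   "fraction",  "static",    30, "nearest",  "land-use"),
    f("landcov",   "class",     "static",   300, "nearest",  "land-use"),
    f("artland",   "km",        "static",   100, "bilinear", "land-use"),
    f("daylength", "h",         "daily",     NA, "bilinear", "temporal")
  )
}

#' Relative humidity from air and dew-point temperature
#'
#' Computes relative humidity as the ratio of saturation vapour pressures at
#' the dew point and at the air temperature, using a Magnus-form saturation
#' curve \eqn{e_s(T) = a \exp(b T / (c + T))}. Because only the ratio enters,
#' the result is insensitive to `a`. Values are clipped to `[0, 100]` so
#' super-saturation artifacts (`d2m > t2m`) cannot exceed 100%.
#'
#' @param t2m air temperature, degrees C (numeric vector/array or
#'   `raster_stack`).
#' @param d2m dew-point temperature, same shape as `t2m`.
#' @param constants Magnus constants `c(a, b, c)`; `a` in hPa, `c` in degrees
#'   C. The default set (6.112, 17.62, 243.12) is a widely used calibration;
#'   it is exposed so an alternative saturation formula can be swapped in.
#' @return relative humidity in percent, same container type as the input.
#' @examples
#' relative_humidity(15, 15)  # 100
#' relative_humidity(20, 10)
#' @export
relative_humidity <- function(t2m, d2m,
                              constants = c(a = 6.112, b = 17.62, c = 243.12)) {
  if (inherits(t2m, "raster_stack")) {
    out <- t2m
    out$values <- relative_humidity(t2m$values,
                                    if (inherits(d2m, "raster_stack"))
                                      d2m$values else d2m,
                                    constants)
    out$feature_name <- "rh"; out$units <- "%"
    return(out)
  }
  if (!identical(dim(t2m) %||% length(t2m), dim(d2m) %||% length(d2m)))
    stop_gridta("t2m and d2m shapes differ")
  b <- constants[["b"]]; cc <- constants[["c"]]
  es <- function(temp) exp(b * temp / (cc + temp))  # 'a' cancels in the ratio
  rh <- 100 * es(d2m) / es(t2m)
  rh[] <- pmin(pmax(rh, 0), 100)
  rh
}

# solar declination in degrees for a day of year
solar_declination <- function(doy) -23.44 * cos(2 * pi * (doy + 10) / 365.24)

#' Day length and noon solar zenith angle
#'
#' Daylight hours from the standard solar declination / hour-angle model. The
#' hour-angle argument is clipped to `[-1, 1]`, so polar day and night resolve
#' to 24 h and 0 h respectively.
#'
#' @param latitude degrees, south negative; `|latitude| <= 90`.
#' @param date a `Date` (or coercible); recycled against `latitude`.
#' @return hours of daylight in `(0, 24)` (or exactly 0/24 at the poles).
#' @examples
#' day_length(0, as.Date("2017-03-21"))       # ~12 h
#' day_length(-23.55, as.Date("2017-12-21"))  # austral summer, > 12 h
#' @export
day_length <- function(latitude, date) {
  stopifnot(all(abs(latitude) <= 90))
  doy <- as.integer(format(as_date(date), "%j"))
  decl <- solar_declination(doy) * pi / 180
  lat <- latitude * pi / 180
  x <- pmin(pmax(-tan(lat) * tan(decl), -1), 1)
  24 * acos(x) / pi
}

#' @rdname day_length
#' @return `solar_zenith_noon` gives the solar zenith angle at local solar
#'   noon, degrees (the angular distance between latitude and declination).
#' @export
solar_zenith_noon <- function(latitude, date) {
  doy <- as.integer(format(as_date(date), "%j"))
  abs(latitude - solar_declination(doy))
}

#' Terrain slope from a DEM
#'
#' Slope in degrees from elevation change over each cell's four-connected
#' neighbours: central differences where both neighbours are available,
#' one-sided differences at edges or next to missing cells, zero where no
#' neighbour is available along an axis.
#'
#' @param dem a static (single-slice) `raster_stack` of elevation in metres.
#' @param cell_size metres; taken from the DEM grid when omitted.
#' @return a static `raster_stack` named `"slope"`, degrees.
#' @export
slope_from_dem <- function(dem, cell_size = NULL) {
  stopifnot(inherits(dem, "raster_stack"))
  if (!is_static(dem)) stop_gridta("dem must be a static (single-slice) stack")
  z <- stack_slice(dem, 1L)
  if (all(is.na(z))) stop_gridta("all-missing DEM")
  h <- cell_size %||% dem$grid$cell_size
  nr <- nrow(z); nc <- ncol(z)
  pad <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  axis_grad <- function(plus, minus) {
    g <- (plus - minus) / (2 * h)                 # central
    one_p <- (plus - z) / h                       # one-sided forward
    one_m <- (z - minus) / h                      # one-sided backward
    g[is.na(g)] <- one_p[is.na(g)]
    g[is.na(g)] <- one_m[is.na(g)]
    g[is.na(g)] <- 0
    g
  }
  gx <- axis_grad(pad(z, 0, 1), pad(z, 0, -1))    # west -> east
  gy <- axis_grad(pad(z, -1, 0), pad(z, 1, 0))    # south -> north (row 1 north)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  raster_stack(dem$grid, dem$times, slope, "slope", "deg")
}

#' Resample a stack onto a target grid
#'
#' Samples the source stack at the target grid's cell centres. `"nearest"`
#' copies the value of the source cell containing each target centre;
#' `"bilinear"` interpolates the four surrounding source cell centres
#' (clamping to the edge centres inside the source extent, so no overshoot is
#' possible) and propagates missingness when any participating source cell is
#' missing. Target centres outside the source extent become missing.
#'
#' @param stack source `raster_stack`.
#' @param target target [grid_definition()].
#' @param method `"nearest"` or `"bilinear"`.
#' @return a `raster_stack` on `target` with the source time axis.
#' @export
resample_to_grid <- function(stack, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- stack$grid
  if (same_grid(src, target)) {
    out <- stack; out$grid <- target
    return(out)
  }
  tx <- cell_centre_x(target, rep(seq_len(target$n_cols),
                                  each = target$n_rows))
  ty <- cell_centre_y(target, rep(seq_len(target$n_rows),
                                  times = target$n_cols))
  # extent check (half-open)
  inside <- tx >= src$origin_x & tx < src$origin_x + src$n_cols * src$cell_size &
            ty >= src$origin_y & ty < src$origin_y + src$n_rows * src$cell_size
  if (!any(inside)) stop_gridta("source and target extents are disjoint")
  nt <- length(stack$times)
  out <- array(NA_real_, dim = c(nt, target$n_rows, target$n_cols))
  flat <- function(row, col) (col - 1L) * src$n_rows + row  # column-major slice
  if (method == "nearest") {
    rc <- point_to_cell(src, tx, ty)
    ok <- inside & !is.na(rc$row)
    for (t in seq_len(nt)) {
      sl <- stack_slice(stack, t)
      vals <- rep(NA_real_, length(tx))
      vals[ok] <- sl[cbind(rc$row[ok], rc$col[ok])]
      out[t, , ] <- matrix(vals, target$n_rows, target$n_cols)
    }
  } else {
    # continuous (row, col) index of each target centre in source centre space
    u <- (tx - src$origin_x) / src$cell_size + 0.5            # col index
    v <- src$n_rows - (ty - src$origin_y) / src$cell_size + 0.5  # row index
    c0 <- pmin(pmax(floor(u), 1), src$n_cols)
    c1 <- pmin(c0 + 1, src$n_cols)
    r0 <- pmin(pmax(floor(v), 1), src$n_rows)
    r1 <- pmin(r0 + 1, src$n_rows)
    wc <- pmin(pmax(u - c0, 0), 1)
    wr <- pmin(pmax(v - r0, 0), 1)
    for (t in seq_len(nt)) {
      sl <- stack_slice(stack, t)
      v00 <- sl[cbind(r0, c0)]; v01 <- sl[cbind(r0, c1)]
      v10 <- sl[cbind(r1, c0)]; v11 <- sl[cbind(r1, c1)]
      vals <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
              wr * ((1 - wc) * v10 + wc * v11)
      vals[!inside] <- NA_real_
      out[t, , ] <- matrix(vals, target$n_rows, target$n_cols)
    }
  }
  raster_stack(target, stack$times, out, stack$feature_name, stack$units)
}

#' Interpolate a stack onto a daily calendar
#'
#' Cell-wise linear interpolation in time between the stack's native slices
#' onto every day of `calendar`. Before the first and after the last native
#' slice the nearest slice is held constant (no trend extrapolation). Static
#' stacks broadcast unchanged onto the calendar.
#'
#' @param stack a `raster_stack`.
#' @param calendar ordered `Date` vector of target days.
#' @return a daily `raster_stack` on the same grid.
#' @export
temporal_interpolate_daily <- function(stack, calendar) {
  calendar <- as_date(calendar)
  if (length(calendar) == 0L) stop_gridta("empty calendar")
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols
  nt <- length(stack$times); nd <- length(calendar)
  vin <- matrix(stack$values, nt, nr * nc)  # time x cell
  if (nt == 1L) {
    vout <- matrix(rep(vin, each = nd), nd, nr * nc)
  } else {
    tx <- as.numeric(stack$times); dx <- as.numeric(calendar)
    vout <- matrix(NA_real_, nd, nr * nc)
    for (cell in seq_len(nr * nc)) {
      y <- vin[, cell]; ok <- !is.na(y)
      if (!any(ok)) next
      if (sum(ok) == 1L) vout[, cell] <- y[ok]
      else vout[, cell] <- stats::approx(tx[ok], y[ok], xout = dx,
                                         rule = 2)$y
    }
  }
  raster_stack(stack$grid, calendar,
               array(vout, dim = c(nd, nr, nc)),
               stack$feature_name, stack$units)
}

#' Fill gaps in a stack from space-time neighbourhoods
#'
#' Iteratively replaces each missing cell by the mean of available values in
#' its 3 x 3 x 3 space-time neighbourhood, repeating until nothing is missing
#' or `max_iter` passes have run. Gaps that remain are filled with the
#' per-day spatial mean, and finally the global mean. Observed values are
#' never altered.
#'
#' @param stack a `raster_stack` with at least one non-missing value.
#' @param max_iter maximum neighbourhood passes.
#' @return the filled `raster_stack`.
#' @export
gap_fill <- function(stack, max_iter = 10) {
  v <- stack$values
  if (all(is.na(v))) stop_gridta("fully-missing stack")
  dims <- dim(v)
  offsets <- expand.grid(dt = -1:1, dr = -1:1, dc = -1:1)
  shift3 <- function(a, dt, dr, dc) {
    out <- array(NA_real_, dims)
    ti <- seq_len(dims[1]) + dt; ri <- seq_len(dims[2]) + dr
    ci <- seq_len(dims[3]) + dc
    okt <- ti >= 1 & ti <= dims[1]; okr <- ri >= 1 & ri <= dims[2]
    okc <- ci >= 1 & ci <= dims[3]
    out[okt, okr, okc] <- a[ti[okt], ri[okr], ci[okc], drop = FALSE]
    out
  }
  iter <- 0L
  while (anyNA(v) && iter < max_iter) {
    s <- array(0, dims); n <- array(0L, dims)
    for (k in seq_len(nrow(offsets))) {
      sh <- shift3(v, offsets$dt[k], offsets$dr[k], offsets$dc[k])
      ok <- !is.na(sh)
      s[ok] <- s[ok] + sh[ok]
      n <- n + ok
    }
    fill <- is.na(v) & n > 0L
    v[fill] <- s[fill] / n[fill]
    iter <- iter + 1L
  }
  if (anyNA(v)) {
    day_mean <- apply(v, 1, mean, na.rm = TRUE)
    for (t in seq_len(dims[1])) {
      sl <- v[t, , ]
      if (anyNA(sl) && is.finite(day_mean[t])) sl[is.na(sl)] <- day_mean[t]
      v[t, , ] <- sl
    }
    v[is.na(v)] <- mean(v, na.rm = TRUE)
  }
  out <- stack; out$values <- v
  out
}

# centres of a fine static mask's TRUE cells, as an n x 2 matrix of (x, y)
mask_centres <- function(mask) {
  sl <- stack_slice(mask, 1L)
  idx <- which(!is.na(sl) & sl > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(x = cell_centre_x(mask$grid, idx[, "col"]),
        y = cell_centre_y(mask$grid, idx[, "row"]))
}

# min distance (m) from points to mask-cell centres; chunked brute force
min_dist_to_mask <- function(px, py, centres) {
  out <- rep(Inf, length(px))
  step <- 2048L
  for (i0 in seq(1L, length(px), by = step)) {
    ii <- i0:min(i0 + step - 1L, length(px))
    d2 <- outer(px[ii], centres[, "x"], "-")^2 +
          outer(py[ii], centres[, "y"], "-")^2
    out[ii] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Fraction of each grid cell within a buffer of a feature mask
#'
#' Morphologically dilates a fine-resolution binary mask by `radius_m`
#' (a fine pixel is in the buffer when its centre lies within `radius_m` of
#' any mask pixel centre) and aggregates to the target grid as the fraction
#' of each target cell's fine pixels inside the buffer.
#'
#' @param feature_mask static fine-resolution `raster_stack`, non-zero where
#'   the feature (e.g. a lake perimeter) is present.
#' @param target target [grid_definition()].
#' @param radius_m buffer radius in metres (e.g. 200 or 400).
#' @return a static `raster_stack` of fractions in `[0, 1]` on `target`.
#' @export
buffer_fraction <- function(feature_mask, target, radius_m) {
  stopifnot(radius_m > 0)
  centres <- mask_centres(feature_mask)
  fg <- feature_mask$grid
  fx <- cell_centre_x(fg, rep(seq_len(fg$n_cols), each = fg$n_rows))
  fy <- cell_centre_y(fg, rep(seq_len(fg$n_rows), times = fg$n_cols))
  if (is.null(centres)) {
    message("buffer_fraction: empty feature mask; returning all-zero field")
    inbuf <- rep(FALSE, length(fx))
  } else {
    inbuf <- min_dist_to_mask(fx, fy, centres) <= radius_m
  }
  rc <- point_to_cell(target, fx, fy)
  ok <- !is.na(rc$row)
  cell_id <- (rc$col[ok] - 1L) * target$n_rows + rc$row[ok]
  tot <- tabulate(cell_id, nbins = n_cells(target))
  hit <- tabulate(cell_id[inbuf[ok]], nbins = n_cells(target))
  frac <- ifelse(tot > 0, hit / tot, NA_real_)
  vals <- matrix(frac, target$n_rows, target$n_cols)
  raster_stack(target, feature_mask$times[1],
               array(vals, c(1L, target$n_rows, target$n_cols)),
               paste0("b", radius_m, "m"), "fraction")
}

#' Distance from each grid cell centre to the nearest feature cell
#'
#' Euclidean centre-to-centre distance on the metric plane, in kilometres.
#'
#' @param target target [grid_definition()].
#' @param feature_mask static `raster_stack`, non-zero at feature cells.
#' @return a static `raster_stack` of distances in km on `target`.
#' @export
distance_to_feature <- function(target, feature_mask) {
  centres <- mask_centres(feature_mask)
  if (is.null(centres)) stop_gridta("empty feature mask")
  tx <- cell_centre_x(target, rep(seq_len(target$n_cols),
                                  each = target$n_rows))
  ty <- cell_centre_y(target, rep(seq_len(target$n_rows),
                                  times = target$n_cols))
  d <- min_dist_to_mask(tx, ty, centres) / 1000
  raster_stack(target, feature_mask$times[1],
               array(matrix(d, target$n_rows, target$n_cols),
                     c(1L, target$n_rows, target$n_cols)),
               "distance", "km")
}

#' Calendar-quarter averaging of a stack
#'
#' Replaces each cell's daily values by the mean of its available values in
#' the enclosing calendar quarter (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec),
#' assigned to every day of that quarter. Used for noisy optical predictors
#' such as NDVI, whose daily retrievals are cloud-contaminated. Quarters with
#' no data stay missing.
#'
#' @param stack a `raster_stack`.
#' @param window months per averaging block; the default 3 gives calendar
#'   quarters (other values are not implemented).
#' @return a `raster_stack` on the same time axis.
#' @export
seasonal_average <- function(stack, window = 3) {
  if (window != 3) stop_gridta("only 3-month (calendar quarter) windows are implemented")
  qtr <- paste0(format(stack$times, "%Y"), "Q",
                (as.integer(format(stack$times, "%m")) - 1L) %/% 3L + 1L)
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols
  v <- matrix(stack$values, length(stack$times), nr * nc)
  for (q in unique(qtr)) {
    rows <- qtr == q
    m <- colMeans(v[rows, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    v[rows, ] <- matrix(m, sum(rows), nr * nc, byrow = TRUE)
  }
  out <- stack
  out$values <- array(v, dim = dim(stack$values))
  out
}

#' Harmonize a raw stack to the analysis grid and daily calendar
#'
#' Convenience composition of [resample_to_grid()] and
#' [temporal_interpolate_daily()]; the operation is idempotent on stacks that
#' are already daily and on-grid.
#'
#' @param stack a `raster_stack` at native resolution.
#' @param target target [grid_definition()].
#' @param calendar daily `Date` calendar.
#' @param method resampling method, see [resample_to_grid()].
#' @return a daily `raster_stack` on `target` (static stacks stay static).
#' @export
harmonize_stack <- function(stack, target, calendar,
                            method = c("bilinear", "nearest")) {
  out <- resample_to_grid(stack, target, match.arg(method))
  if (is_static(out)) out else temporal_interpolate_daily(out, calendar)
}
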