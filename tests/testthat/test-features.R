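# Derived predictors and raster harmonization.

test_that("relative humidity follows the Magnus ratio and clips correctly", {
  expect_equal(relative_humidity(15, 15), 100)
  expect_equal(relative_humidity(10, 12), 100)  # super-saturation clipped
  expect_equal(relative_humidity(20, 10), oracle_rh(20, 10),
               tolerance = 1e-9)
  # vectorized over random pairs, matched to the hand-written formula
  set.seed(1)
  t2m <- runif(50, -5, 35); d2m <- t2m - runif(50, 0, 15)
  expect_equal(relative_humidity(t2m, d2m),
               vapply(seq_along(t2m), function(i) oracle_rh(t2m[i], d2m[i]),
                      numeric(1)),
               tolerance = 1e-9)
  expect_error(relative_humidity(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("rh on generated worlds never needs the clip (d2m <= t2m)", {
  w <- tiny_world()
  expect_true(all(w$predictors$d2m$values <= w$predictors$t2m$values))
  rh <- w$predictors$rh$values
  expect_true(all(rh >= 0 & rh <= 100))
  # raw ratio without clipping stays below 100 when d2m <= t2m
  raw <- 100 * exp(17.62 * w$predictors$d2m$values /
                     (243.12 + w$predictors$d2m$values)) /
    exp(17.62 * w$predictors$t2m$values / (243.12 + w$predictors$t2m$values))
  expect_true(all(raw <= 100 + 1e-12))
})

test_that("day length matches the declination model and its limits", {
  expect_equal(day_length(0, as.Date("2017-05-10")), 12, tolerance = 0.2)
  expect_gt(day_length(-23.55, as.Date("2017-12-21")),
            day_length(-23.55, as.Date("2017-06-21")))
  expect_equal(day_length(-23.55, as.Date("2017-03-21")),
               oracle_daylength(-23.55, as.Date("2017-03-21")),
               tolerance = 1e-6)
  # polar clipping
  expect_equal(day_length(-90, as.Date("2017-06-21")), 0)
  expect_equal(day_length(-90, as.Date("2017-12-21")), 24)
  expect_error(day_length(95, as.Date("2017-01-01")))
})

test_that("slope handles flat, planar and random DEMs", {
  g <- grid_definition(5, 5, cell_size = 500)
  flat <- raster_stack(g, as.Date("2016-01-01"), matrix(100, 5, 5), "dem", "m")
  expect_true(all(slope_from_dem(flat)$values == 0))
  # plane rising 50 m per cell eastward: slope = atan(50/500) exactly
  plane <- raster_stack(g, as.Date("2016-01-01"),
                        matrix(rep(50 * (0:4), each = 5), 5, 5), "dem", "m")
  sl <- slope_from_dem(plane)
  expect_equal(as.vector(sl$values),
               rep(atan(50 / 500) * 180 / pi, 25), tolerance = 1e-12)
  # random DEM (with a missing hole) against the brute-force stencil
  set.seed(42)
  z <- matrix(rnorm(25, 700, 50), 5, 5)
  z[2, 3] <- NA
  dem <- raster_stack(g, as.Date("2016-01-01"), z, "dem", "m")
  expect_equal(matrix(slope_from_dem(dem)$values[1, , ], 5, 5),
               oracle_slope(z, 500), tolerance = 1e-12)
  allna <- raster_stack(g, as.Date("2016-01-01"),
                        matrix(NA_real_, 5, 5), "dem", "m")
  expect_error(slope_from_dem(allna), "missing")
})

test_that("resampling reproduces identity, midpoints and a brute-force oracle", {
  g2 <- grid_definition(2, 2, cell_size = 100)
  sl <- matrix(c(0, 10, 0, 10), 2, 2)  # south row 10, north row 0
  src <- raster_stack(g2, as.Date("2016-01-01"), sl, "x", "")
  # identity on identical grids
  expect_equal(resample_to_grid(src, g2, "bilinear")$values, src$values)
  expect_equal(resample_to_grid(src, g2, "nearest")$values, src$values)
  # midpoint of {0,10} corners is 5: a 1x1 target centred mid-grid
  gmid <- grid_definition(1, 1, cell_size = 100, origin_x = 50, origin_y = 50)
  expect_equal(as.vector(resample_to_grid(src, gmid, "bilinear")$values), 5)
  # random 4x4 -> 7x7 bilinear against pointwise oracle
  set.seed(7)
  g4 <- grid_definition(4, 4, cell_size = 100)
  z <- matrix(rnorm(16), 4, 4)
  s4 <- raster_stack(g4, as.Date("2016-01-01"), z, "x", "")
  g7 <- grid_definition(7, 7, cell_size = 55, origin_x = 3, origin_y = 2)
  got <- resample_to_grid(s4, g7, "bilinear")
  for (r in 1:7) for (c in 1:7) {
    expect_equal(got$values[1, r, c],
                 oracle_bilinear(z, g4, gridta:::cell_centre_x(g7, c),
                                 gridta:::cell_centre_y(g7, r)),
                 tolerance = 1e-12)
  }
  # no overshoot for bilinear; nearest draws from the exact source value set
  expect_true(min(got$values, na.rm = TRUE) >= min(z))
  expect_true(max(got$values, na.rm = TRUE) <= max(z))
  nn <- resample_to_grid(s4, g7, "nearest")
  expect_true(all(nn$values[!is.na(nn$values)] %in% z))
  # disjoint extents error
  gfar <- grid_definition(2, 2, cell_size = 100, origin_x = 1e6, origin_y = 1e6)
  expect_error(resample_to_grid(s4, gfar, "bilinear"), "disjoint")
})

test_that("bilinear propagates missing source corners", {
  g4 <- grid_definition(4, 4, cell_size = 100)
  z <- matrix(1, 4, 4); z[2, 2] <- NA
  s4 <- raster_stack(g4, as.Date("2016-01-01"), z, "x", "")
  # the target centre (140, 340) sits in the non-missing cell (1, 2) but its
  # bilinear stencil touches the missing cell (2, 2)
  gt <- grid_definition(1, 1, cell_size = 100, origin_x = 90, origin_y = 290)
  expect_true(is.na(resample_to_grid(s4, gt, "bilinear")$values[1, 1, 1]))
  expect_false(is.na(resample_to_grid(s4, gt, "nearest")$values[1, 1, 1]))
})

test_that("temporal interpolation is linear inside and flat outside", {
  g <- grid_definition(2, 2, cell_size = 500)
  days <- as.Date("2016-01-01") + c(0, 2)
  v <- array(c(10, 20), dim = c(2, 1, 1))[, rep(1, 2), rep(1, 2), drop = FALSE]
  dim(v) <- c(2, 2, 2)
  v[1, , ] <- 10; v[2, , ] <- 20
  stk <- raster_stack(g, days, v, "x", "")
  cal <- as.Date("2016-01-01") + 0:4
  out <- temporal_interpolate_daily(stk, cal)
  expect_equal(out$values[2, 1, 1], 15)          # midpoint
  expect_equal(out$values[4, 1, 1], 20)          # held flat beyond the end
  # single slice broadcasts
  st1 <- raster_stack(g, days[1], matrix(3, 2, 2), "x", "")
  expect_true(all(temporal_interpolate_daily(st1, cal)$values == 3))
  # random 3-slice series per cell against the hand-rolled piecewise oracle
  set.seed(8)
  days3 <- as.Date("2016-01-01") + c(0, 5, 11)
  v3 <- array(rnorm(3 * 4), dim = c(3, 2, 2))
  stk3 <- raster_stack(g, days3, v3, "x", "")
  cal2 <- as.Date("2016-01-01") + 0:13
  out3 <- temporal_interpolate_daily(stk3, cal2)
  for (r in 1:2) for (c in 1:2)
    expect_equal(out3$values[, r, c],
                 oracle_pwl(as.numeric(days3), v3[, r, c], as.numeric(cal2)),
                 tolerance = 1e-12)
  expect_error(temporal_interpolate_daily(stk, as.Date(character(0))),
               "empty")
})

test_that("gap filling preserves data and fills from neighbourhoods", {
  g <- grid_definition(3, 3, cell_size = 500)
  days <- as.Date("2016-01-01") + 0:2
  v <- array(7, dim = c(3, 3, 3))
  stk <- raster_stack(g, days, v, "x", "")
  expect_equal(gap_fill(stk)$values, v)          # nothing to do
  v2 <- v; v2[2, 2, 2] <- NA
  stk2 <- raster_stack(g, days, v2, "x", "")
  filled <- gap_fill(stk2)
  expect_equal(filled$values[2, 2, 2], 7)        # constant neighbourhood
  expect_equal(filled$values[-14], v[-14])       # observed values untouched
  expect_error(gap_fill(raster_stack(g, days, array(NA_real_, c(3, 3, 3)),
                                     "x", "")), "missing")
})

test_that("gap filling recovers a smooth field within local variability", {
  w <- tiny_world()
  lst <- w$predictors$lst
  miss <- is.na(lst$values)
  expect_gt(sum(miss), 0)  # the generator punched cloud gaps
  filled <- gap_fill(lst)
  expect_false(anyNA(filled$values))
  # truth = the pre-cloud lst values; regenerate the clean world layer
  cfg <- w$config; cfg$missing_frac_target <- 0
  clean <- generate_world(cfg)$predictors$lst
  err <- abs(filled$values[miss] - clean$values[miss])
  local_sd <- sd(diff(as.vector(clean$values[, 5, 5])))
  expect_lt(stats::median(err), 2 * local_sd)
})

test_that("buffer fractions and distances agree with per-pixel geometry", {
  fine <- grid_definition(20, 20, cell_size = 10)
  m <- matrix(0, 20, 20); m[9:12, 9:12] <- 1
  mask <- raster_stack(fine, as.Date("2016-01-01"), m, "mask", "")
  coarse <- grid_definition(2, 2, cell_size = 100)
  bf <- buffer_fraction(mask, coarse, 30)
  # brute force: count fine pixels within 30 m of any mask pixel centre
  ctr <- which(m == 1, arr.ind = TRUE)
  cx <- gridta:::cell_centre_x(fine, ctr[, 2])
  cy <- gridta:::cell_centre_y(fine, ctr[, 1])
  for (R in 1:2) for (C in 1:2) {
    hits <- 0
    for (r in 1:20) for (c in 1:20) {
      px <- gridta:::cell_centre_x(fine, c); py <- gridta:::cell_centre_y(fine, r)
      cell <- gridta:::point_to_cell(coarse, px, py)
      if (cell$row != R || cell$col != C) next
      if (min(sqrt((px - cx)^2 + (py - cy)^2)) <= 30) hits <- hits + 1
    }
    expect_equal(bf$values[1, R, C], hits / 100)
  }
  # full mask -> fraction 1 everywhere
  full <- raster_stack(fine, as.Date("2016-01-01"),
                       matrix(1, 20, 20), "mask", "")
  expect_true(all(buffer_fraction(full, coarse, 30)$values == 1))
  # empty mask -> all zero, message not error
  none <- raster_stack(fine, as.Date("2016-01-01"),
                       matrix(0, 20, 20), "mask", "")
  expect_message(z <- buffer_fraction(none, coarse, 30), "empty")
  expect_true(all(z$values == 0))
  # distances: on-feature 0; elsewhere exact centre-to-centre; oracle scan
  d <- distance_to_feature(coarse, mask)
  set.seed(9)
  msp <- matrix(runif(400) < 0.05, 20, 20) + 0
  msk2 <- raster_stack(fine, as.Date("2016-01-01"), msp, "mask", "")
  d2 <- distance_to_feature(coarse, msk2)
  ctr2 <- which(msp == 1, arr.ind = TRUE)
  for (R in 1:2) for (C in 1:2) {
    px <- gridta:::cell_centre_x(coarse, C); py <- gridta:::cell_centre_y(coarse, R)
    best <- Inf
    for (i in seq_len(nrow(ctr2))) {
      dd <- sqrt((px - gridta:::cell_centre_x(fine, ctr2[i, 2]))^2 +
                 (py - gridta:::cell_centre_y(fine, ctr2[i, 1]))^2)
      best <- min(best, dd)
    }
    expect_equal(d2$values[1, R, C], best / 1000, tolerance = 1e-12)
  }
  expect_error(distance_to_feature(coarse, none), "empty")
})

test_that("seasonal averaging pools calendar quarters", {
  g <- grid_definition(1, 1, cell_size = 500)
  cal <- seq(as.Date("2016-01-01"), as.Date("2016-12-31"), by = "day")
  const <- raster_stack(g, cal, array(4, c(length(cal), 1, 1)), "ndvi", "")
  expect_true(all(seasonal_average(const)$values == 4))
  set.seed(10)
  v <- array(rnorm(length(cal)), c(length(cal), 1, 1))
  v[sample(length(cal), 60), 1, 1] <- NA
  stk <- raster_stack(g, cal, v, "ndvi", "")
  out <- seasonal_average(stk)
  qtr <- (as.integer(format(cal, "%m")) - 1) %/% 3 + 1
  for (q in 1:4) {
    expected <- mean(v[qtr == q, 1, 1], na.rm = TRUE)
    expect_equal(unique(out$values[qtr == q, 1, 1]), expected,
                 tolerance = 1e-12)
  }
})

test_that("harmonization is idempotent on already-daily on-grid stacks", {
  w <- tiny_world()
  t2m <- w$predictors$t2m
  out <- harmonize_stack(t2m, w$grid, w$calendar)
  expect_equal(out$values, t2m$values)
  expect_equal(out$times, t2m$times)
})
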