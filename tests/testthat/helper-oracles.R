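# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (per-element loops, closed forms) and never call the
# implementation paths they check.

oracle_rmse <- function(obs, pred) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (obs[i] - pred[i])^2
  sqrt(s / length(obs))
}

oracle_r2 <- function(obs, pred) {
  mo <- mean(obs); mp <- mean(pred)
  num <- sum((obs - mo) * (pred - mp))
  (num / sqrt(sum((obs - mo)^2) * sum((pred - mp)^2)))^2
}

# closed-form simple OLS of y on x
oracle_ols <- function(y, x) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b, r2 = stats::cor(y, x)^2)
}

# Magnus-form relative humidity, written out directly
oracle_rh <- function(t2m, d2m, b = 17.62, cc = 243.12) {
  es <- function(temp) 6.112 * exp(b * temp / (cc + temp))
  min(max(100 * es(d2m) / es(t2m), 0), 100)
}

# declination/hour-angle day length, written out directly
oracle_daylength <- function(lat, date) {
  doy <- as.integer(format(date, "%j"))
  decl <- (-23.44 * cos(2 * pi * (doy + 10) / 365.24)) * pi / 180
  x <- -tan(lat * pi / 180) * tan(decl)
  x <- min(max(x, -1), 1)
  24 * acos(x) / pi
}

# per-cell four-neighbour slope stencil (degrees)
oracle_slope <- function(z, h) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  gval <- function(c0, p, m) {         # centre, plus-neighbour, minus-neighbour
    if (!is.na(p) && !is.na(m)) (p - m) / (2 * h)
    else if (!is.na(p)) (p - c0) / h
    else if (!is.na(m)) (c0 - m) / h
    else 0
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    e <- if (c < nc) z[r, c + 1] else NA
    w <- if (c > 1) z[r, c - 1] else NA
    n <- if (r > 1) z[r - 1, c] else NA
    s <- if (r < nr) z[r + 1, c] else NA
    gx <- gval(z[r, c], e, w)
    gy <- gval(z[r, c], n, s)
    out[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

# bilinear sample of a source slice at a point, edge-clamped centre lattice
oracle_bilinear <- function(sl, src, x, y) {
  if (x < src$origin_x || x >= src$origin_x + src$n_cols * src$cell_size ||
      y < src$origin_y || y >= src$origin_y + src$n_rows * src$cell_size)
    return(NA_real_)
  u <- (x - src$origin_x) / src$cell_size + 0.5
  v <- src$n_rows - (y - src$origin_y) / src$cell_size + 0.5
  c0 <- min(max(floor(u), 1), src$n_cols); c1 <- min(c0 + 1, src$n_cols)
  r0 <- min(max(floor(v), 1), src$n_rows); r1 <- min(r0 + 1, src$n_rows)
  wc <- min(max(u - c0, 0), 1); wr <- min(max(v - r0, 0), 1)
  (1 - wr) * ((1 - wc) * sl[r0, c0] + wc * sl[r0, c1]) +
    wr * ((1 - wc) * sl[r1, c0] + wc * sl[r1, c1])
}

# 1-D piecewise-linear interpolation with flat extrapolation
oracle_pwl <- function(tx, ty, xout) {
  vapply(xout, function(x) {
    if (x <= tx[1]) return(ty[1])
    if (x >= tx[length(tx)]) return(ty[length(ty)])
    i <- max(which(tx <= x))
    if (tx[i] == x) return(ty[i])
    ty[i] + (ty[i + 1] - ty[i]) * (x - tx[i]) / (tx[i + 1] - tx[i])
  }, numeric(1))
}

# synthetic obs-pred station-day panel for decomposition tests
make_obs_pred <- function(n_st = 6, years = 2015:2016, sd_obs = 3) {
  days <- seq(as.Date(paste0(min(years), "-01-01")),
              as.Date(paste0(max(years), "-12-31")), by = "day")
  set.seed(23)
  do.call(rbind, lapply(seq_len(n_st), function(i)
    data.frame(station_id = sprintf("s%d", i), date = days,
               ta_obs = 20 + 2 * i / n_st +
                 5 * cos(2 * pi * as.integer(format(days, "%j")) / 365) +
                 rnorm(length(days), 0, sd_obs))))
}

# independent greedy forward selection using cv_score as the scoring primitive
oracle_greedy_ffs <- function(table, candidates, hp, folds, seed,
                              learner = "rf") {
  sel <- character(0); rem <- candidates; traj <- numeric(0)
  repeat {
    if (length(rem) == 0) break
    scores <- vapply(rem, function(f)
      cv_score(table, c(sel, f), hp, folds, seed, learner)$rmse, numeric(1))
    i <- which.min(scores)
    if (length(sel) > 0 && !(traj[length(traj)] - scores[i] > 0)) break
    sel <- c(sel, rem[i]); traj <- c(traj, unname(scores[i])); rem <- rem[-i]
  }
  list(selected = sel, trajectory = traj)
}

# Sampling SE of OLS estimates implied by the known generating process:
# Var(b) = (X'X)^-1 [sigma^2 X'X + Xs' C Xs] (X'X)^-1, where Xs are
# per-station column sums and C is the spatial covariance of station field
# values, obtained by Monte Carlo over field realizations.
oracle_recovery_se <- function(X, station_id, stations, cfg, nrep = 500) {
  ids <- unique(station_id)
  stn <- stations[match(ids, stations$station_id), ]
  idx <- cbind(stn$row, stn$col)
  M <- matrix(0, nrep, length(ids))
  set.seed(424242)
  sigma_cells <- cfg$spatial_range / cfg$cell_size_m
  for (r in seq_len(nrep)) {
    f <- gridta:::gaussian_smooth(matrix(rnorm(cfg$n_rows * cfg$n_cols),
                                         cfg$n_rows, cfg$n_cols), sigma_cells)
    f <- f / sd(f) * cfg$field_sd
    M[r, ] <- f[idx]
  }
  Cst <- stats::cov(M)
  xs <- t(vapply(ids, function(u)
    colSums(X[station_id == u, , drop = FALSE]), numeric(ncol(X))))
  XtX_inv <- solve(crossprod(X))
  V <- XtX_inv %*% (cfg$noise_sd^2 * crossprod(X) + t(xs) %*% Cst %*% xs) %*%
    XtX_inv
  sqrt(diag(V))
}
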