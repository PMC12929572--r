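# Validation statistics: RMSE/R^2 by stratum, external validation,
# permutation importance on held-out stations, spatial/temporal error
# decomposition and model-vs-model prediction deltas.

#' Root mean square error
#'
#' @param obs,pred equal-length finite numeric vectors, degrees C.
#' @return `sqrt(mean((obs - pred)^2))`.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) == 0) stop_gridta("empty input")
  if (length(obs) != length(pred)) stop_gridta("length mismatch")
  sqrt(mean((obs - pred)^2))
}

#' Coefficient of determination
#'
#' The reported R^2 is the squared Pearson correlation of observed and
#' predicted values — the convention of an observed-vs-predicted scatter
#' with a fitted regression line. `r_squared_ss` gives the alternative
#' `1 - SSE/SST` definition for comparison.
#'
#' @inheritParams rmse
#' @return a dimensionless value in `[0, 1]` (for `r_squared`).
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) < 2) stop_gridta("need at least 2 points")
  if (length(obs) != length(pred)) stop_gridta("length mismatch")
  if (sd(obs) == 0 || sd(pred) == 0) stop_gridta("zero variance input")
  stats::cor(obs, pred)^2
}

#' @rdname r_squared
#' @export
r_squared_ss <- function(obs, pred) {
  if (length(obs) < 2) stop_gridta("need at least 2 points")
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Out-of-fold predictions under station-grouped CV
#'
#' Runs ten-fold (by default) leave-location-out CV and returns one
#' out-of-fold prediction per row, tagged with station, date and fold; the
#' input to [build_metrics_report()] and [decompose_error()].
#'
#' @inheritParams cv_score
#' @return a data frame `station_id`, `date`, `urban`, `fold`, `ta_obs`,
#'   `pred`.
#' @export
station_cv_predict <- function(table, features, hp = hyper_params(),
                               folds, seed = 1L, learner = "rf") {
  cv_predictions(table, features, hp, folds, seed, learner)
}

metric_row <- function(obs, pred) {
  data.frame(
    n = length(obs),
    rmse = rmse(obs, pred),
    r2 = if (length(obs) >= 2 && sd(obs) > 0 && sd(pred) > 0)
      r_squared(obs, pred) else NA_real_,
    mean_delta = mean(obs - pred),
    sd_delta = if (length(obs) >= 2) sd(obs - pred) else NA_real_
  )
}

#' Stratified accuracy report
#'
#' RMSE, R^2, n, and the mean and SD of `obs - pred` overall and stratified
#' by year, month (pooled across years), urbanicity and station. Strata with
#' fewer than two rows report `NA` for R^2 (RMSE is still computed).
#'
#' @param pred_table obs-pred table with `station_id`, `date`, `urban`,
#'   `ta_obs`, `pred` (see [station_cv_predict()]).
#' @return a list of class `metrics_report` of data frames: `overall`,
#'   `by_year`, `by_month`, `by_urban`, `by_station`.
#' @export
build_metrics_report <- function(pred_table) {
  stopifnot(all(c("station_id", "date", "ta_obs", "pred") %in%
                  names(pred_table)))
  strat <- function(key) {
    parts <- split(pred_table, key)
    out <- do.call(rbind, lapply(parts, function(p)
      metric_row(p$ta_obs, p$pred)))
    out <- cbind(data.frame(stratum = names(parts)), out)
    rownames(out) <- NULL
    out
  }
  out <- list(
    overall = metric_row(pred_table$ta_obs, pred_table$pred),
    by_year = strat(format(as_date(pred_table$date), "%Y")),
    by_month = strat(format(as_date(pred_table$date), "%m")),
    by_urban = if (all(is.na(pred_table$urban))) NULL else
      strat(ifelse(pred_table$urban, "urban", "rural")),
    by_station = strat(pred_table$station_id)
  )
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall: RMSE %.3f degC, R2 %.3f (n = %d)\n",
              x$overall$rmse, x$overall$r2, x$overall$n))
  if (!is.null(x$by_urban)) {
    for (i in seq_len(nrow(x$by_urban)))
      cat(sprintf("  %-6s RMSE %.3f, R2 %.3f (n = %d)\n",
                  x$by_urban$stratum[i], x$by_urban$rmse[i],
                  x$by_urban$r2[i], x$by_urban$n[i]))
  }
  invisible(x)
}

#' External validation on hold-out stations
#'
#' Predicts the hold-out rows with a final fitted model and reports overall
#' and per-station metrics.
#'
#' @param model a `ta_fit` (or [ta_model()]).
#' @param holdout training-table rows of the hold-out stations.
#' @return a `metrics_report`.
#' @export
external_validate <- function(model, holdout) {
  if (inherits(model, "ta_model")) model <- model$fit
  if (nrow(holdout) == 0) stop_gridta("empty holdout")
  p <- predict(model, holdout)
  tab <- data.frame(station_id = holdout$station_id, date = holdout$date,
                    urban = if ("urban" %in% names(holdout)) holdout$urban
                    else NA,
                    ta_obs = holdout$ta_obs, pred = p)
  build_metrics_report(tab)
}

ols_line <- function(y, x) {
  if (length(x) < 2 || sd(x) == 0)
    return(data.frame(r2 = NA_real_, intercept = NA_real_, slope = NA_real_,
                      n = length(x)))
  fit <- lm(y ~ x)
  data.frame(r2 = if (sd(y) == 0) NA_real_ else stats::cor(y, x)^2,
             intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
             n = length(x))
}

#' Spatial and temporal decomposition of prediction error
#'
#' Separates a model's skill at reproducing between-station annual mean
#' temperature (spatial component) from its skill at daily anomalies around
#' those annual means (temporal component). For each station-year with at
#' least `min_days` available days, observed and predicted annual means are
#' computed; then, per year and overall, observed quantities are regressed
#' on predicted ones (observed is the response):
#' * temporal: `obs - obs annual mean` on `pred - pred annual mean`;
#' * spatial: station-year observed annual means on predicted annual means.
#'
#' Each regression is summarized by R^2, intercept (degrees C) and slope.
#'
#' @param pred_table obs-pred table with `station_id`, `date`, `ta_obs`,
#'   `pred`.
#' @param min_days minimum available days for a station-year to enter the
#'   decomposition (incomplete years give noisy annual means).
#' @return a list of class `decomposition_result` with data frames
#'   `spatial` and `temporal`, one row per year plus `"overall"`.
#' @export
decompose_error <- function(pred_table, min_days = 300) {
  d <- pred_table
  d$year <- format(as_date(d$date), "%Y")
  key <- interaction(d$station_id, d$year, drop = TRUE)
  nd <- tapply(d$ta_obs, key, length)
  keep_key <- names(nd)[nd >= min_days]
  d <- d[key %in% keep_key, , drop = FALSE]
  if (nrow(d) == 0)
    stop_gridta("no station-year with >= ", min_days, " days")
  key <- interaction(d$station_id, d$year, drop = TRUE)
  obs_mean <- tapply(d$ta_obs, key, mean)
  pred_mean <- tapply(d$pred, key, mean)
  d$obs_anom <- d$ta_obs - obs_mean[as.character(key)]
  d$pred_anom <- d$pred - pred_mean[as.character(key)]
  ann <- data.frame(key = names(obs_mean),
                    year = sub("^.*\\.", "", names(obs_mean)),
                    obs = as.numeric(obs_mean), pred = as.numeric(pred_mean))
  if (length(unique(d$station_id)) < 2)
    warning("single station: spatial component is undefined")
  years <- sort(unique(d$year))
  one <- function(fun) {
    rows <- lapply(c(years, "overall"), function(y) {
      cbind(data.frame(year = y), fun(y))
    })
    do.call(rbind, rows)
  }
  temporal <- one(function(y) {
    sel <- if (y == "overall") rep(TRUE, nrow(d)) else d$year == y
    ols_line(d$obs_anom[sel], d$pred_anom[sel])
  })
  spatial <- one(function(y) {
    sel <- if (y == "overall") rep(TRUE, nrow(ann)) else ann$year == y
    ols_line(ann$obs[sel], ann$pred[sel])
  })
  structure(list(spatial = spatial, temporal = temporal,
                 station_years = ann),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  ov_s <- x$spatial[x$spatial$year == "overall", ]
  ov_t <- x$temporal[x$temporal$year == "overall", ]
  cat(sprintf(paste0(
    "<decomposition_result>\n",
    "  spatial : R2 %.3f, intercept %+.3f, slope %.3f\n",
    "  temporal: R2 %.3f, intercept %+.3f, slope %.3f\n"),
    ov_s$r2, ov_s$intercept, ov_s$slope,
    ov_t$r2, ov_t$intercept, ov_t$slope))
  invisible(x)
}

#' Permutation feature importance on held-out data
#'
#' Mean decrease in accuracy: the baseline score (R^2 by default, RMSE by
#' flag) of the model on the hold-out rows, minus the score after randomly
#' permuting one predictor's values within the hold-out, averaged over
#' `n_iter` shuffles per feature. For the RMSE score the sign is flipped so
#' larger importance still means a more influential feature.
#'
#' @param model a `ta_fit` (or [ta_model()]).
#' @param holdout hold-out training-table rows.
#' @param n_iter shuffles per feature.
#' @param seed RNG seed.
#' @param score `"r2"` or `"rmse"`.
#' @return a list of class `importance_result` with `importance` (a data
#'   frame sorted by decreasing mean importance), `baseline`, `n_iter`,
#'   `score`.
#' @export
permutation_importance <- function(model, holdout, n_iter = 10, seed = 1L,
                                   score = c("r2", "rmse")) {
  score <- match.arg(score)
  if (inherits(model, "ta_model")) model <- model$fit
  if (nrow(holdout) == 0) stop_gridta("empty holdout")
  check <- setdiff(model$features, names(holdout))
  if (length(check) > 0)
    stop_gridta("holdout lacks feature(s): ", paste(check, collapse = ", "))
  sc <- function(obs, pred)
    if (score == "r2") r_squared(obs, pred) else -rmse(obs, pred)
  base_pred <- predict(model, holdout)
  baseline <- sc(holdout$ta_obs, base_pred)
  set.seed(seed)
  imp <- vapply(model$features, function(f) {
    drops <- vapply(seq_len(n_iter), function(i) {
      h <- holdout
      h[[f]] <- sample(h[[f]])
      baseline - sc(h$ta_obs, predict(model, h))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  ord <- order(imp, decreasing = TRUE)
  structure(list(
    importance = data.frame(feature = model$features[ord],
                            importance = unname(imp[ord])),
    baseline = baseline, n_iter = n_iter, score = score, seed = seed
  ), class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> baseline %s = %.3f (%d iterations)\n",
              x$score, x$baseline, x$n_iter))
  for (i in seq_len(nrow(x$importance)))
    cat(sprintf("  %-12s %+.4f\n", x$importance$feature[i],
                x$importance$importance[i]))
  invisible(x)
}

#' Cellwise difference of two prediction stacks
#'
#' `pred_a - pred_b` on identical grids and time axes — e.g. random-forest
#' minus linear-baseline predictions. Aggregate with [aggregate_cube()].
#'
#' @param pred_a,pred_b `raster_stack`s on the same grid and times.
#' @return a `raster_stack` of differences.
#' @export
delta_temp <- function(pred_a, pred_b) {
  if (!same_grid(pred_a$grid, pred_b$grid) ||
      !identical(pred_a$times, pred_b$times))
    stop_gridta("grids or time axes differ")
  out <- pred_a
  out$values <- pred_a$values - pred_b$values
  out$feature_name <- "delta_ta"
  out
}
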