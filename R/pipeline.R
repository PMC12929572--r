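# Full-grid prediction, temporal aggregation, and the end-to-end pipeline
# runner that stitches the stages together reproducibly.

#' Predict daily temperature over the full grid
#'
#' Assembles the per-cell feature matrix for each day from the harmonized
#' stacks and predicts with the fitted model. Cells with any missing feature
#' value propagate to missing predictions.
#'
#' @param model a `ta_fit` or [ta_model()].
#' @param stacks named list of daily (or static) `raster_stack`s on one grid,
#'   covering every model feature.
#' @param calendar days to predict; defaults to the time axis of the first
#'   daily stack.
#' @return a `raster_stack` of predicted Ta (degrees C) with a `manifest`
#'   attribute recording features, learner kind and hyperparameters.
#' @export
predict_grid <- function(model, stacks, calendar = NULL) {
  if (inherits(model, "ta_model")) model <- model$fit
  miss <- setdiff(model$features, names(stacks))
  if (length(miss) > 0)
    stop_gridta("missing feature stack(s): ", paste(miss, collapse = ", "))
  stacks <- stacks[model$features]
  grid <- stacks[[1]]$grid
  for (s in stacks) if (!same_grid(s$grid, grid))
    stop_gridta("all stacks must share one grid")
  if (is.null(calendar)) {
    daily <- stacks[!vapply(stacks, is_static, logical(1))]
    if (length(daily) == 0) stop_gridta("no daily stack to take a calendar from")
    calendar <- daily[[1]]$times
  }
  calendar <- as_date(calendar)
  nr <- grid$n_rows; nc <- grid$n_cols
  ncell <- nr * nc
  out <- array(NA_real_, c(length(calendar), nr, nc))
  static_mat <- lapply(stacks, function(s)
    if (is_static(s)) as.vector(stack_slice(s, 1L)) else NULL)
  for (ti in seq_along(calendar)) {
    day <- calendar[ti]
    X <- matrix(NA_real_, ncell, length(stacks),
                dimnames = list(NULL, names(stacks)))
    for (f in names(stacks)) {
      s <- stacks[[f]]
      if (is_static(s)) X[, f] <- static_mat[[f]]
      else {
        j <- match(day, s$times)
        if (is.na(j)) stop_gridta("stack '", f, "' lacks day ", format(day))
        X[, f] <- as.vector(stack_slice(s, j))
      }
    }
    ok <- stats::complete.cases(X)
    pred <- rep(NA_real_, ncell)
    if (any(ok))
      pred[ok] <- predict(model, as.data.frame(X[ok, , drop = FALSE]))
    out[ti, , ] <- matrix(pred, nr, nc)
  }
  cube <- raster_stack(grid, calendar, out, "ta_pred", "degC")
  attr(cube, "manifest") <- list(
    kind = model$kind, features = model$features,
    hyperparams = if (!is.null(model$hp)) unclass(model$hp) else NULL,
    seed = model$seed, n_train = model$n)
  cube
}

#' Aggregate a daily prediction cube in time
#'
#' Per-cell means over calendar months, years, or the whole period, ignoring
#' missing slices; the number of contributing days per cell is returned as a
#' companion stack.
#'
#' @param cube a daily `raster_stack` (e.g. from [predict_grid()]).
#' @param period `"month"`, `"year"` or `"all"`.
#' @return a list with `mean` and `n_days` `raster_stack`s, one slice per
#'   period (labelled by its first day).
#' @export
aggregate_cube <- function(cube, period = c("month", "year", "all")) {
  period <- match.arg(period)
  key <- switch(period,
    month = format(cube$times, "%Y-%m"),
    year = format(cube$times, "%Y"),
    all = rep("all", length(cube$times)))
  groups <- split(seq_along(cube$times), key)
  nr <- cube$grid$n_rows; nc <- cube$grid$n_cols
  m <- array(NA_real_, c(length(groups), nr, nc))
  n <- array(0, c(length(groups), nr, nc))
  for (i in seq_along(groups)) {
    sub <- cube$values[groups[[i]], , , drop = FALSE]
    m[i, , ] <- apply(sub, c(2, 3), function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    })
    n[i, , ] <- apply(sub, c(2, 3), function(v) sum(!is.na(v)))
  }
  times <- as.Date(vapply(groups, function(g)
    format(min(cube$times[g])), character(1)))
  ord <- order(times)
  list(
    mean = raster_stack(cube$grid, times[ord],
                        m[ord, , , drop = FALSE],
                        paste0(cube$feature_name, "_", period, "_mean"),
                        cube$units),
    n_days = raster_stack(cube$grid, times[ord],
                          n[ord, , , drop = FALSE], "n_days", "days")
  )
}

#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: the synthetic world (or input
#' paths), feature candidates, the hyperparameter grid, selection and fold
#' seeds, and the learner. Round-trips losslessly through JSON.
#'
#' @param world a [world_config()].
#' @param candidates candidate features for selection; `NULL` to skip
#'   selection and use `features`.
#' @param features features to fit when selection is skipped.
#' @param grid hyperparameter grid (list of [hyper_params()]); `NULL` for a
#'   single fit at `hyper`.
#' @param hyper fallback [hyper_params()].
#' @param learner `"rf"`, `"mlr"` or `"both"`.
#' @param holdout_frac hold-out station fraction.
#' @param k CV folds.
#' @param tol FFS stopping tolerance.
#' @param tuning_frac stratified subsample fraction for selection (`NULL` for
#'   the full table).
#' @param gap_fill_optical gap-fill cloud gaps in optical stacks?
#' @param predict_grid run full-grid prediction and aggregation?
#' @param seed master analysis seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(world = world_config(),
                       candidates = NULL,
                       features = names(default_coefficients()),
                       grid = NULL, hyper = hyper_params(),
                       learner = c("both", "rf", "mlr"),
                       holdout_frac = 0.10, k = 10, tol = 0,
                       tuning_frac = NULL,
                       gap_fill_optical = TRUE,
                       predict_grid = FALSE, seed = 1L) {
  structure(list(world = world, candidates = candidates, features = features,
                 grid = grid, hyper = hyper, learner = match.arg(learner),
                 holdout_frac = holdout_frac, k = k, tol = tol,
                 tuning_frac = tuning_frac,
                 gap_fill_optical = gap_fill_optical,
                 predict_grid = predict_grid, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the pipeline end to end
#'
#' Simulate (or accept) a world, harmonize optical gaps, assemble the
#' station-day table, split off the hold-out stations, select/fit the
#' learner(s), cross-validate, externally validate, decompose the error,
#' compute permutation importance and (optionally) predict the full grid.
#' All artifacts are returned and, when `dir` is given, serialized as
#' CSV/JSON with a run manifest.
#'
#' @param config a [run_config()].
#' @param dataset optionally a pre-generated `synthetic_dataset` (skips
#'   generation).
#' @param dir optional output directory for artifacts.
#' @return a list of class `pipeline_result` with the dataset, table,
#'   partition, folds, models (`rf` and/or `mlr`), metrics, decomposition,
#'   importance and (optionally) prediction aggregates.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL, dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (is.null(dataset)) dataset <- generate_world(config$world)

  stacks <- dataset$predictors
  if (config$gap_fill_optical) {
    for (f in intersect(c("lst", "ndvi"), names(stacks)))
      if (anyNA(stacks[[f]]$values))
        stacks[[f]] <- gap_fill(stacks[[f]])
  }

  table <- extract_station_values(stacks, station_table(dataset))
  part <- select_holdout_stations(table, frac = config$holdout_frac,
                                  seed = seed)
  train <- table[table$station_id %in% part$training_station_ids, ]
  holdout <- table[table$station_id %in% part$holdout_station_ids, ]
  folds <- make_station_folds(part$training_station_ids, k = config$k,
                              seed = seed)

  fit_one <- function(learner) {
    ta_model(train,
             features = if (is.null(config$candidates)) config$features,
             candidates = config$candidates,
             learner = learner, hyper = config$hyper, grid = config$grid,
             folds = folds, tol = config$tol,
             tuning_frac = config$tuning_frac, seed = seed)
  }
  models <- list()
  if (config$learner %in% c("rf", "both")) models$rf <- fit_one("rf")
  if (config$learner %in% c("mlr", "both")) {
    # the baseline reuses the features selected for the forest
    feats <- if (!is.null(models$rf)) models$rf$features else config$features
    models$mlr <- ta_model(train, features = feats, learner = "mlr",
                           folds = folds, seed = seed)
  }
  primary <- models[[if (config$learner == "mlr") "mlr" else "rf"]]

  external <- lapply(models, function(m) external_validate(m, holdout))
  # on short calendars, require most of the period instead of 300 days
  min_days <- min(300, max(1L, floor(0.6 * length(dataset$calendar))))
  decomposition <- lapply(models, function(m)
    decompose_error(m$cv, min_days = min_days))
  importance <- if (!is.null(models$rf))
    permutation_importance(models$rf, holdout, seed = seed) else NULL

  prediction <- NULL
  if (isTRUE(config$predict_grid)) {
    cube <- predict_grid(primary, stacks, dataset$calendar)
    prediction <- list(cube = cube,
                       annual = aggregate_cube(cube, "year"),
                       monthly = aggregate_cube(cube, "month"))
  }

  out <- structure(list(
    config = config, dataset = dataset, table = table,
    partition = part, folds = folds, models = models,
    cv_metrics = lapply(models, function(m) m$cv_metrics),
    external = external, decomposition = decomposition,
    importance = importance, prediction = prediction
  ), class = "pipeline_result")
  if (!is.null(dir)) write_pipeline_result(out, dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (k in names(x$models)) {
    m <- x$models[[k]]
    cat(sprintf("  %s: CV RMSE %.3f / R2 %.3f; external RMSE %.3f / R2 %.3f\n",
                k, m$cv_metrics$overall$rmse, m$cv_metrics$overall$r2,
                x$external[[k]]$overall$rmse, x$external[[k]]$overall$r2))
  }
  invisible(x)
}

metrics_to_list <- function(r) lapply(unclass(r), function(d)
  if (is.null(d)) NULL else d)

write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wjson <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, dataframe = "rows",
    force = TRUE, null = "null")
  tab <- result$table
  tab$date <- format(tab$date)
  write.csv(tab, file.path(dir, "training_table.csv"), row.names = FALSE)
  wjson(unclass(result$partition), "partition.json")
  wjson(as.list(result$folds), "folds.json")
  for (k in names(result$models)) {
    wjson(metrics_to_list(result$cv_metrics[[k]]),
          paste0("metrics_cv_", k, ".json"))
    wjson(metrics_to_list(result$external[[k]]),
          paste0("metrics_external_", k, ".json"))
    wjson(result$decomposition[[k]][c("spatial", "temporal")],
          paste0("decomposition_", k, ".json"))
    cvt <- result$models[[k]]$cv
    cvt$date <- format(cvt$date)
    write.csv(cvt, file.path(dir, paste0("cv_predictions_", k, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(result$importance))
    wjson(result$importance[c("importance", "baseline", "n_iter", "score")],
          "importance.json")
  manifest <- list(
    seed = result$config$seed,
    world_seed = result$config$world$seed,
    learner = result$config$learner,
    n_rows_table = nrow(result$table),
    n_stations = length(unique(result$table$station_id)),
    features = lapply(result$models, function(m) m$features))
  wjson(manifest, "manifest.json")
  invisible(dir)
}
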