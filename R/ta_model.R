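# The user-facing modelling front-end: fit, select, cross-validate and
# report through one classed object.

#' Fit a daily air-temperature model
#'
#' The central fitting function. Given a station-day training table (see
#' [extract_station_values()]), optionally selects features and
#' hyperparameters by joint forward feature selection and grid search under
#' station-grouped CV, runs leave-location-out cross-validation for
#' reporting, and fits the final learner on all training rows.
#'
#' @param data training table with `ta_obs`, `station_id`, `date`, `urban`
#'   and feature columns.
#' @param features predictor names to use directly (skip selection).
#' @param candidates candidate names for forward feature selection; when
#'   given, selection is run (over `grid` if supplied, else at `hyper`).
#' @param learner `"rf"` (random forest) or `"mlr"` (linear baseline).
#' @param hyper a [hyper_params()]; ignored when a grid search picks its own.
#' @param grid optional list of [hyper_params()] for the joint search.
#' @param folds optional station-fold assignment; built with
#'   [make_station_folds()] (`k` folds) when omitted.
#' @param k number of CV folds.
#' @param tol forward-selection stopping tolerance (degrees C of RMSE).
#' @param tuning_frac optional stratified subsampling fraction applied to the
#'   table used for selection only (the study design uses 0.5 to cut search
#'   cost), see [stratified_sample()].
#' @param cv run the final cross-validation for reporting?
#' @param seed master seed.
#' @return an object of class `ta_model` with components `fit` (the final
#'   `ta_fit`), `features`, `hyper`, `selection` (if run), `cv`
#'   (out-of-fold prediction table), `cv_metrics`, `folds`, `nobs`.
#' @seealso [external_validate()], [permutation_importance()],
#'   [decompose_error()], [predict_grid()]
#' @export
ta_model <- function(data, features = NULL, candidates = NULL,
                     learner = c("rf", "mlr"), hyper = hyper_params(),
                     grid = NULL, folds = NULL, k = 10, tol = 0,
                     tuning_frac = NULL, cv = TRUE, seed = 1L) {
  learner <- match.arg(learner)
  cl <- match.call()
  if (is.null(features) && is.null(candidates))
    stop_gridta("supply either features or candidates")
  if (is.null(folds))
    folds <- make_station_folds(unique(data$station_id), k = k, seed = seed)

  selection <- NULL
  if (!is.null(candidates)) {
    tune_tab <- if (!is.null(tuning_frac))
      stratified_sample(data, frac = tuning_frac, seed = seed) else data
    if (!is.null(grid)) {
      selection <- grid_search_ffs(tune_tab, candidates, grid, folds,
                                   tol = tol, seed = seed, learner = learner)
      features <- selection$best$selected_features
      hyper <- selection$best$hyperparams
    } else {
      selection <- forward_feature_select(tune_tab, candidates, hyper, folds,
                                          tol = tol, seed = seed,
                                          learner = learner)
      features <- selection$selected_features
    }
  }

  cv_tab <- NULL; cv_metrics <- NULL
  if (cv) {
    cv_tab <- station_cv_predict(data, features, hyper, folds, seed, learner)
    cv_metrics <- build_metrics_report(cv_tab)
  }
  fit <- fit_learner(data, features, hyper, seed, learner)
  fitted_vals <- predict(fit, data)

  structure(list(
    kind = learner, fit = fit, features = features,
    hyper = if (learner == "rf") hyper else NULL,
    selection = selection, folds = folds,
    cv = cv_tab, cv_metrics = cv_metrics,
    fitted = fitted_vals, obs = data$ta_obs,
    nobs = nrow(data), seed = seed, call = cl
  ), class = "ta_model")
}

#' @export
print.ta_model <- function(x, ...) {
  cat(sprintf("<ta_model> %s on %d station-day rows\n", x$kind, x$nobs))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  if (!is.null(x$hyper)) cat("  hyperparameters:", format(x$hyper), "\n")
  if (!is.null(x$cv_metrics))
    cat(sprintf("  station-grouped CV: RMSE %.3f degC, R2 %.3f\n",
                x$cv_metrics$overall$rmse, x$cv_metrics$overall$r2))
  invisible(x)
}

#' @export
summary.ta_model <- function(object, ...) {
  out <- list(kind = object$kind, features = object$features,
              hyper = object$hyper, nobs = object$nobs,
              cv_metrics = object$cv_metrics,
              train_rmse = rmse(object$obs, object$fitted),
              train_r2 = r_squared(object$obs, object$fitted),
              decomposition = if (!is.null(object$cv) &&
                                  length(unique(object$cv$station_id)) >= 2)
                tryCatch(decompose_error(object$cv, min_days = 1),
                         error = function(e) NULL) else NULL)
  class(out) <- "summary.ta_model"
  out
}

#' @export
print.summary.ta_model <- function(x, ...) {
  cat(sprintf("Daily air-temperature model (%s), n = %d\n", x$kind, x$nobs))
  cat("Features:", paste(x$features, collapse = ", "), "\n")
  if (!is.null(x$hyper)) cat("Hyperparameters:", format(x$hyper), "\n")
  cat(sprintf("Training fit: RMSE %.3f degC, R2 %.3f\n",
              x$train_rmse, x$train_r2))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("Station-grouped CV: RMSE %.3f degC, R2 %.3f (n = %d)\n",
                x$cv_metrics$overall$rmse, x$cv_metrics$overall$r2,
                x$cv_metrics$overall$n))
    if (!is.null(x$cv_metrics$by_urban))
      for (i in seq_len(nrow(x$cv_metrics$by_urban)))
        cat(sprintf("  %-6s RMSE %.3f, R2 %.3f\n",
                    x$cv_metrics$by_urban$stratum[i],
                    x$cv_metrics$by_urban$rmse[i],
                    x$cv_metrics$by_urban$r2[i]))
  }
  if (!is.null(x$decomposition)) print(x$decomposition)
  invisible(x)
}

#' @export
coef.ta_model <- function(object, ...) {
  if (object$kind != "mlr")
    stop_gridta("coefficients are only defined for the 'mlr' learner; ",
                "use permutation_importance() for the random forest")
  coef(object$fit$object)
}

#' @export
predict.ta_model <- function(object, newdata, calendar = NULL, ...) {
  if (is.data.frame(newdata)) return(predict(object$fit, newdata))
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1),
                                     "raster_stack")))
    return(predict_grid(object$fit, newdata, calendar))
  stop_gridta("newdata must be a data frame or a named list of raster_stacks")
}

#' @export
residuals.ta_model <- function(object, ...) object$obs - object$fitted

#' @export
fitted.ta_model <- function(object, ...) object$fitted

#' @export
plot.ta_model <- function(x, which = c("cv", "train"), ...) {
  which <- match.arg(which)
  if (which == "cv" && !is.null(x$cv)) {
    obs <- x$cv$ta_obs; pred <- x$cv$pred
    main <- "Observed vs predicted (station-grouped CV)"
  } else {
    obs <- x$obs; pred <- x$fitted
    main <- "Observed vs predicted (training)"
  }
  plot.default(obs, pred, pch = 16, cex = 0.3,
               col = rgb(0, 0, 0, 0.25),
               xlab = "observed Ta (degC)", ylab = "predicted Ta (degC)",
               main = main, ...)
  abline(0, 1, col = "red")
  abline(lm(pred ~ obs), col = "blue", lty = 2)
  invisible(x)
}
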