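# Learners, station-grouped CV scoring, forward feature selection and the
# joint hyperparameter grid search; `ta_model()` is the user-facing fitting
# front-end.

#' Random-forest hyperparameters
#'
#' @param n_estimators number of trees.
#' @param max_features `"auto"` (all p features at each split, the regression
#'   convention) or `"sqrt"` (`ceiling(sqrt(p))`).
#' @param max_depth maximum tree depth; `NA` for unbounded.
#' @param min_node_size minimum node size eligible for splitting (the
#'   regression default 5; 1 grows trees to purity).
#' @return a list of class `hyper_params`.
#' @export
hyper_params <- function(n_estimators = 1000, max_features = "sqrt",
                         max_depth = 15, min_node_size = 5) {
  stopifnot(n_estimators >= 1, max_features %in% c("auto", "sqrt"),
            is.na(max_depth) || max_depth >= 1, min_node_size >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = max_features,
                 max_depth = max_depth,
                 min_node_size = as.integer(min_node_size)),
            class = "hyper_params")
}

#' @export
format.hyper_params <- function(x, ...)
  sprintf("trees=%d, max_features=%s, depth=%s", x$n_estimators,
          x$max_features, x$max_depth)

#' @export
print.hyper_params <- function(x, ...) {
  cat("<hyper_params>", format(x), "\n"); invisible(x)
}

#' The default hyperparameter search grid
#'
#' All combinations of `n_estimators` in {300, 500, 700, 1000},
#' `max_features` in {auto, sqrt} and `max_depth` in {10, 15, 20}: 24 points.
#'
#' @return a list of [hyper_params()].
#' @export
default_hyper_grid <- function() {
  g <- expand.grid(n_estimators = c(300L, 500L, 700L, 1000L),
                   max_features = c("auto", "sqrt"),
                   max_depth = c(10L, 15L, 20L),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    hyper_params(g$n_estimators[i], g$max_features[i], g$max_depth[i]))
}

mtry_from <- function(hp, p) {
  if (hp$max_features == "sqrt") min(max(ceiling(sqrt(p)), 1L), p) else p
}

check_features <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss) > 0)
    stop_gridta("missing feature column(s): ", paste(miss, collapse = ", "))
  bad <- features[vapply(features,
                         function(f) any(!is.finite(table[[f]])), logical(1))]
  if (length(bad) > 0)
    stop_gridta("non-finite values in feature(s): ",
                paste(bad, collapse = ", "))
}

#' Fit the random-forest learner
#'
#' Bootstrap-aggregated regression trees (via ranger) with squared-error
#' splitting; predictions are the arithmetic mean over trees. Deterministic
#' for a fixed seed (single-threaded).
#'
#' @param table training table with `ta_obs` and the feature columns.
#' @param features ordered character vector of predictor names.
#' @param hp a [hyper_params()].
#' @param seed RNG seed for the forest.
#' @return a fitted model of class `ta_fit` (kind `"rf"`).
#' @export
train_rf <- function(table, features, hp = hyper_params(), seed = 1L) {
  stopifnot(length(features) >= 1)
  check_features(table, features)
  x <- table[, features, drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = table$ta_obs,
    num.trees = hp$n_estimators,
    mtry = mtry_from(hp, length(features)),
    min.node.size = hp$min_node_size %||% 5L,
    max.depth = if (is.na(hp$max_depth)) 0 else hp$max_depth,
    seed = seed, num.threads = 1, verbose = FALSE
  )
  structure(list(kind = "rf", features = features, object = fit, hp = hp,
                 seed = seed, n = nrow(table)),
            class = "ta_fit")
}

#' Fit the multiple-linear-regression baseline
#'
#' Ordinary least squares with an intercept on exactly the supplied features
#' (typically those selected for the random forest, for comparability).
#'
#' @inheritParams train_rf
#' @return a fitted model of class `ta_fit` (kind `"mlr"`).
#' @export
train_mlr <- function(table, features) {
  stopifnot(length(features) >= 1)
  check_features(table, features)
  d <- table[, c("ta_obs", features), drop = FALSE]
  fit <- lm(ta_obs ~ ., data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_gridta("rank-deficient design; collinear column(s): ",
                paste(bad, collapse = ", "))
  }
  structure(list(kind = "mlr", features = features, object = fit,
                 hp = NULL, seed = NA_integer_, n = nrow(table)),
            class = "ta_fit")
}

#' @export
predict.ta_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) > 0)
    stop_gridta("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  nd <- newdata[, object$features, drop = FALSE]
  if (object$kind == "rf")
    predict(object$object, data = nd, num.threads = 1)$predictions
  else
    unname(predict(object$object, newdata = nd))
}

#' @export
print.ta_fit <- function(x, ...) {
  cat(sprintf("<ta_fit> %s on %d rows, %d feature(s)%s\n", x$kind, x$n,
              length(x$features),
              if (!is.null(x$hp)) paste0(" [", format(x$hp), "]") else ""))
  invisible(x)
}

fit_learner <- function(table, features, hp, seed, learner = "rf") {
  if (learner == "rf") train_rf(table, features, hp, seed)
  else train_mlr(table, features)
}

#' Station-grouped cross-validation score
#'
#' For each fold, fits the learner on the out-of-fold stations and predicts
#' the fold's rows; RMSE and R^2 are computed on the pooled out-of-fold
#' predictions (the scatter-plot convention, not a per-fold average).
#'
#' @param table training table with `ta_obs`, `station_id` and features.
#' @param features predictor names.
#' @param hp a [hyper_params()] (ignored for the `"mlr"` learner).
#' @param folds named fold assignment from [make_station_folds()].
#' @param seed RNG seed for the forests.
#' @param learner `"rf"` or `"mlr"`.
#' @return a list `(rmse, r2, n)`.
#' @export
cv_score <- function(table, features, hp, folds, seed = 1L, learner = "rf") {
  pred <- cv_predictions(table, features, hp, folds, seed, learner)
  list(rmse = rmse(pred$ta_obs, pred$pred),
       r2 = r_squared(pred$ta_obs, pred$pred),
       n = nrow(pred))
}

# shared CV engine: pooled out-of-fold prediction table
cv_predictions <- function(table, features, hp, folds, seed = 1L,
                           learner = "rf") {
  stopifnot(length(features) >= 1)
  fold_of <- folds[match(table$station_id, names(folds))]
  if (anyNA(fold_of))
    stop_gridta("rows from station(s) without a fold: ",
                paste(unique(table$station_id[is.na(fold_of)]), collapse = ", "))
  out <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    test <- fold_of == f
    if (!any(test)) stop_gridta("fold ", f, " has zero rows")
    fit <- fit_learner(table[!test, , drop = FALSE], features, hp,
                       seed + f, learner)
    p <- predict(fit, table[test, , drop = FALSE])
    out[[f]] <- data.frame(station_id = table$station_id[test],
                           date = table$date[test],
                           urban = if ("urban" %in% names(table))
                             table$urban[test] else NA,
                           fold = f,
                           ta_obs = table$ta_obs[test], pred = p)
  }
  do.call(rbind, out)
}

#' Forward feature selection under grouped CV
#'
#' Greedy search: the first step scores every single candidate and keeps the
#' best; each later step scores adding each remaining candidate to the
#' current set and keeps the best addition. The search stops when the best
#' addition no longer improves the CV RMSE by more than `tol` (default 0:
#' any strict improvement continues) or candidates are exhausted. The
#' selected subset is the trajectory prefix with minimal RMSE.
#'
#' @inheritParams cv_score
#' @param candidates character vector of candidate features.
#' @param tol minimum RMSE improvement to accept a further feature.
#' @param start `"single"` starts from the best single feature (the
#'   convention of the sequential selector the method is modelled on);
#'   `"pair"` starts from the best pair.
#' @return a list of class `ffs_result`: `selected_features`,
#'   `trajectory` (per-step feature, RMSE, R^2), `cv_rmse_best`, `cv_r2_best`,
#'   `hyperparams`.
#' @export
forward_feature_select <- function(table, candidates, hp, folds, tol = 0,
                                   seed = 1L, learner = "rf",
                                   start = c("single", "pair")) {
  start <- match.arg(start)
  stopifnot(length(candidates) >= 1)
  candidates <- unique(candidates)
  selected <- character(0)
  remaining <- candidates
  traj <- list()
  best_rmse <- Inf

  score_set <- function(feats) cv_score(table, feats, hp, folds, seed, learner)

  if (start == "pair" && length(candidates) >= 2) {
    pairs <- utils::combn(candidates, 2, simplify = FALSE)
    sc <- lapply(pairs, score_set)
    i <- which.min(vapply(sc, `[[`, numeric(1), "rmse"))
    selected <- pairs[[i]]
    remaining <- setdiff(candidates, selected)
    best_rmse <- sc[[i]]$rmse
    traj[[1]] <- data.frame(step = 1L,
                            feature = paste(selected, collapse = "+"),
                            rmse = sc[[i]]$rmse, r2 = sc[[i]]$r2)
  }

  repeat {
    if (length(remaining) == 0) break
    sc <- lapply(remaining, function(f) score_set(c(selected, f)))
    rmses <- vapply(sc, `[[`, numeric(1), "rmse")
    i <- which.min(rmses)
    improvement <- best_rmse - rmses[i]
    first_step <- length(selected) == 0
    if (!first_step && !(improvement > tol)) break
    selected <- c(selected, remaining[i])
    traj[[length(traj) + 1L]] <- data.frame(
      step = length(traj) + 1L, feature = remaining[i],
      rmse = rmses[i], r2 = sc[[i]]$r2)
    best_rmse <- min(best_rmse, rmses[i])
    remaining <- remaining[-i]
  }
  trajectory <- do.call(rbind, traj)
  k <- which.min(trajectory$rmse)
  sel <- if (start == "pair")
    c(strsplit(trajectory$feature[1], "+", fixed = TRUE)[[1]],
      trajectory$feature[seq_len(k)][-1])
  else trajectory$feature[seq_len(k)]
  structure(list(selected_features = sel,
                 trajectory = trajectory,
                 cv_rmse_best = trajectory$rmse[k],
                 cv_r2_best = trajectory$r2[k],
                 hyperparams = hp),
            class = "ffs_result")
}

#' @export
print.ffs_result <- function(x, ...) {
  cat(sprintf("<ffs_result> %d feature(s) [%s], CV RMSE %.3f\n",
              length(x$selected_features),
              paste(x$selected_features, collapse = ", "), x$cv_rmse_best))
  invisible(x)
}

#' Joint grid search over hyperparameters and features
#'
#' Runs [forward_feature_select()] once per grid point and returns all
#' results plus the best pair of (features, hyperparameters) by minimal CV
#' RMSE; exact ties break toward fewer features, then fewer trees, then
#' shallower trees.
#'
#' @inheritParams forward_feature_select
#' @param grid list of [hyper_params()] (default: the 24-point grid).
#' @return a list of class `grid_search_result` with `results` (one
#'   `ffs_result` per grid point) and `best`.
#' @export
grid_search_ffs <- function(table, candidates, grid = default_hyper_grid(),
                            folds, tol = 0, seed = 1L, learner = "rf",
                            start = "single") {
  stopifnot(length(grid) >= 1)
  results <- lapply(grid, function(hp)
    forward_feature_select(table, candidates, hp, folds, tol, seed, learner,
                           start))
  key <- vapply(results, function(r) r$cv_rmse_best, numeric(1))
  nfeat <- vapply(results, function(r) length(r$selected_features), numeric(1))
  ntree <- vapply(grid, function(h) h$n_estimators, numeric(1))
  depth <- vapply(grid, function(h)
    if (is.na(h$max_depth)) Inf else h$max_depth, numeric(1))
  best_i <- order(key, nfeat, ntree, depth)[1]
  structure(list(results = results, grid = grid,
                 best = results[[best_i]], best_index = best_i),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d grid point(s); best: [%s] %s, CV RMSE %.3f\n",
              length(x$results),
              paste(x$best$selected_features, collapse = ", "),
              format(x$best$hyperparams), x$best$cv_rmse_best))
  invisible(x)
}

#' Summarize a grid search as a data frame
#'
#' @param object a `grid_search_result`.
#' @param ... unused.
#' @return one row per grid point: hyperparameters, number and list of
#'   selected features, CV RMSE and R^2.
#' @export
summary.grid_search_result <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$results), function(i) {
    r <- object$results[[i]]; h <- object$grid[[i]]
    data.frame(n_estimators = h$n_estimators, max_features = h$max_features,
               max_depth = h$max_depth,
               n_features = length(r$selected_features),
               features = paste(r$selected_features, collapse = "+"),
               cv_rmse = r$cv_rmse_best, cv_r2 = r$cv_r2_best,
               best = i == object$best_index)
  }))
}
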