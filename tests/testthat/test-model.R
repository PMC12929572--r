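# Learners, CV scoring, forward selection and the grid search.

test_that("a perfect single predictor drives CV error to ~zero", {
  # every station shares the same series, so out-of-fold values are seen in
  # training and deep trees isolate each distinct value exactly
  days <- as.Date("2016-01-01") + 0:49
  set.seed(11)
  vals <- round(rnorm(50, 20, 5), 3)
  tab <- do.call(rbind, lapply(1:20, function(i)
    data.frame(station_id = sprintf("s%d", i), date = days, ta_obs = vals,
               x = vals)))
  folds <- make_station_folds(unique(tab$station_id), k = 4, seed = 1)
  sc <- cv_score(tab, "x", hyper_params(100, "auto", NA, min_node_size = 1),
                 folds, seed = 1)
  expect_lt(sc$rmse, 1e-6)
})

test_that("a pure-noise predictor has no out-of-sample skill", {
  set.seed(12)
  days <- as.Date("2016-01-01") + 0:199
  tab <- do.call(rbind, lapply(1:10, function(i)
    data.frame(station_id = sprintf("s%d", i), date = days,
               ta_obs = rnorm(200, 20, 3), z = rnorm(200))))
  folds <- make_station_folds(unique(tab$station_id), k = 5, seed = 2)
  sc <- cv_score(tab, "z", hyper_params(100, "auto", 10), folds, seed = 2)
  expect_lt(sc$r2, 0.1)
})

test_that("pooled RMSE equals the size-weighted per-fold identity", {
  w <- tiny_world()
  tab <- world_table(w, c("t2m", "lst"))
  folds <- make_station_folds(unique(tab$station_id), k = 4, seed = 3)
  pred <- station_cv_predict(tab, c("t2m", "lst"), folds = folds, seed = 3,
                             learner = "mlr")
  pooled <- rmse(pred$ta_obs, pred$pred)
  per_fold <- vapply(split(pred, pred$fold), function(p)
    c(mse = mean((p$ta_obs - p$pred)^2), n = nrow(p)), numeric(2))
  expect_equal(pooled,
               sqrt(sum(per_fold["mse", ] * per_fold["n", ]) /
                      sum(per_fold["n", ])),
               tolerance = 1e-12)
})

test_that("forward selection matches an independent greedy oracle", {
  w <- clean_world()
  feats <- c("t2m", "lst", "daylength", "noise1", "noise2")
  tab <- world_table(w, feats)
  tab <- tab[tab$date <= as.Date("2016-04-30"), ]  # keep the search cheap
  folds <- make_station_folds(unique(tab$station_id), k = 4, seed = 6)
  hp <- hyper_params(100, "auto", 10)
  got <- forward_feature_select(tab, feats, hp, folds, seed = 6)
  oracle <- oracle_greedy_ffs(tab, feats, hp, folds, seed = 6)
  expect_identical(got$selected_features, oracle$selected)
  expect_equal(got$trajectory$rmse[seq_along(oracle$trajectory)],
               oracle$trajectory, tolerance = 1e-12)
  # trajectory is non-increasing up to its argmin; decoys never selected
  expect_true(all(diff(got$trajectory$rmse) <= 1e-12))
  expect_false(any(c("noise1", "noise2") %in% got$selected_features))
})

test_that("degenerate forward-selection cases behave", {
  w <- clean_world()
  tab <- world_table(w, c("t2m", "noise1"))
  tab <- tab[tab$date <= as.Date("2016-02-29"), ]
  folds <- make_station_folds(unique(tab$station_id), k = 3, seed = 7)
  hp <- hyper_params(50, "auto", 8)
  one <- forward_feature_select(tab, "t2m", hp, folds, seed = 7)
  expect_identical(one$selected_features, "t2m")
  expect_equal(nrow(one$trajectory), 1)
  # the response itself as a candidate is picked first
  tab$self <- tab$ta_obs
  dominant <- forward_feature_select(tab, c("noise1", "self"), hp, folds,
                                     seed = 7)
  expect_equal(dominant$selected_features[1], "self")
})

test_that("the default grid enumerates 24 combinations and ties break first", {
  grid <- default_hyper_grid()
  expect_length(grid, 24)
  combos <- unique(t(vapply(grid, function(h)
    c(h$n_estimators, h$max_features, h$max_depth), character(3))))
  expect_equal(nrow(combos), 24)

  w <- clean_world()
  tab <- world_table(w, c("t2m", "lst"))
  tab <- tab[tab$date <= as.Date("2016-02-29"), ]
  folds <- make_station_folds(unique(tab$station_id), k = 3, seed = 8)
  hp <- hyper_params(50, "auto", 8)
  single <- grid_search_ffs(tab, c("t2m", "lst"), list(hp), folds, seed = 8)
  expect_length(single$results, 1)
  expect_identical(single$best, single$results[[1]])
  twin <- grid_search_ffs(tab, c("t2m", "lst"), list(hp, hp), folds, seed = 8)
  expect_identical(twin$results[[1]], twin$results[[2]])
  expect_equal(twin$best_index, 1L)
  expect_equal(nrow(summary(twin)), 2)
})

test_that("the forest honors its contract", {
  days <- as.Date("2016-01-01") + 0:29
  tab <- do.call(rbind, lapply(1:4, function(i)
    data.frame(station_id = sprintf("s%d", i), date = days, ta_obs = 7,
               x = rnorm(30))))
  m <- train_rf(tab, "x", hyper_params(50, "auto", 5), seed = 1)
  expect_true(all(abs(predict(m, tab) - 7) < 1e-12))  # constant target
  # determinism under a fixed seed
  w <- clean_world()
  wt <- world_table(w, c("t2m", "lst", "daylength"))
  m1 <- train_rf(wt, c("t2m", "lst"), hyper_params(50, "sqrt", 10), seed = 9)
  m2 <- train_rf(wt, c("t2m", "lst"), hyper_params(50, "sqrt", 10), seed = 9)
  probe <- wt[seq(1, nrow(wt), by = 37), ]
  expect_identical(predict(m1, probe), predict(m2, probe))
  # fit capacity on a noise-free linear world
  full <- train_rf(wt, c("t2m", "lst", "daylength"),
                   hyper_params(100, "auto", NA), seed = 9)
  expect_gte(r_squared(wt$ta_obs, predict(full, wt)), 0.99)
  bad <- wt; bad$t2m[1] <- NA
  expect_error(train_rf(bad, "t2m", hyper_params(50, "auto", 5)),
               "non-finite")
})

test_that("the linear baseline is exact OLS", {
  tab <- data.frame(station_id = "s", date = Sys.Date(),
                    x = 1:20, ta_obs = 2 * (1:20) + 1)
  m <- train_mlr(tab, "x")
  expect_equal(unname(coef(m$object)), c(1, 2), tolerance = 1e-9)
  # orthogonal predictors recover their univariate projections
  x1 <- rep(c(-1, 1), 50); x2 <- rep(c(-1, -1, 1, 1), 25)
  set.seed(13)
  y <- 3 * x1 - 2 * x2 + rnorm(100, 0, 0.1)
  tab2 <- data.frame(station_id = "s", date = Sys.Date(), ta_obs = y,
                     x1 = x1, x2 = x2)
  m2 <- train_mlr(tab2, c("x1", "x2"))
  expect_equal(coef(m2$object)[["x1"]], sum(y * x1) / sum(x1^2),
               tolerance = 1e-9)
  expect_equal(coef(m2$object)[["x2"]], sum(y * x2) / sum(x2^2),
               tolerance = 1e-9)
  # row order cannot matter
  perm <- sample(nrow(tab2))
  m3 <- train_mlr(tab2[perm, ], c("x1", "x2"))
  expect_equal(coef(m3$object), coef(m2$object), tolerance = 1e-12)
  # rank deficiency is reported with the offending column
  tab2$x3 <- tab2$x1
  expect_error(train_mlr(tab2, c("x1", "x2", "x3")), "x3")
})

test_that("ta_model wires selection, CV and the final fit together", {
  w <- clean_world()
  feats <- c("t2m", "lst", "noise1")
  tab <- world_table(w, feats)
  tab <- tab[tab$date <= as.Date("2016-03-31"), ]
  m <- ta_model(tab, candidates = feats, learner = "rf",
                hyper = hyper_params(50, "auto", 10), k = 3, seed = 14)
  expect_s3_class(m, "ta_model")
  expect_false("noise1" %in% m$features)
  expect_equal(nrow(m$cv), nrow(tab))
  expect_equal(m$cv_metrics$overall$n, nrow(tab))
  expect_equal(length(residuals(m)), nrow(tab))
  expect_equal(fitted(m) + residuals(m), tab$ta_obs, tolerance = 1e-9)
  expect_output(print(m), "ta_model")
  expect_output(print(summary(m)), "Station-grouped CV")
  expect_error(coef(m), "mlr")
  ml <- ta_model(tab, features = c("t2m", "lst"), learner = "mlr",
                 k = 3, seed = 14)
  expect_named(coef(ml), c("(Intercept)", "t2m", "lst"))
  expect_error(ta_model(tab, learner = "rf"), "features or candidates")
})
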