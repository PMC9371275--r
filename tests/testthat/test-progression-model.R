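test_that("mae implements the mean absolute residual and its invariances", {
  expect_equal(mae(c(10, 20), c(12, 18)), 2)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(c(0, 0, 0), c(1, 2, 3)), 2)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(mae(y + 3.2, yh + 3.2), mae(y, yh))
  expect_error(mae(1:3, 1:4), "equal")
})

test_that("split_cohort is disjoint, exhaustive and seeded", {
  d <- tibble::tibble(x = 1:8)
  sp <- split_cohort(d, test_fraction = 0.25, seed = 1)
  expect_equal(nrow(sp$train), 6)
  expect_equal(nrow(sp$test), 2)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:8)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  sp2 <- split_cohort(d, test_fraction = 0.25, seed = 1)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(split_cohort(d, test_fraction = 1.2), "between 0 and 1")
})

test_that("grid search equals a brute-force loop and is seeded", {
  set.seed(6)
  n <- 80
  X <- tibble::tibble(x0 = rnorm(n), x1 = rnorm(n))
  y <- sin(X$x0 * 2) + 0.5 * X$x1 + rnorm(n, sd = 0.1)
  grid <- list(n_estimators = c(1, 200))
  gs <- grid_search("rf", grid, X, y, seed = 3)
  # independent exhaustive loop over both settings, same paired folds
  folds <- make_cv_folds(n, 5, 3)
  brute <- vapply(grid$n_estimators, function(ne) {
    cv_mae(X, y, model_factory = rf_factory(n_estimators = ne, seed = 3),
           folds = folds)$mean
  }, numeric(1))
  expect_equal(gs$best_params$n_estimators,
               grid$n_estimators[which.min(brute)])
  expect_equal(gs$cv$mean, min(brute))
  expect_equal(sort(gs$results$cv_mae), sort(brute))
  gs2 <- grid_search("rf", grid, X, y, seed = 3)
  expect_identical(gs$best_params, gs2$best_params)
  # one-point grid returns that point
  one <- grid_search("rf", list(n_estimators = 50), X, y, seed = 1)
  expect_equal(one$best_params$n_estimators, 50)
})

test_that("final training at reference hyperparameters fits a smooth signal", {
  set.seed(7)
  n <- 160
  X <- tibble::as_tibble(matrix(rnorm(n * 7), n,
                                dimnames = list(NULL, paste0("f", 1:7))))
  y <- as.matrix(X) %*% c(3, -2, 1.5, 1, -1, 0.5, 0.25)
  y <- as.numeric(y)
  bundle <- train_final(
    "rf",
    list(n_estimators = 291, max_features = 5, max_depth = 30,
         min_samples_split = 7, min_samples_leaf = 2),
    X, y, seed = 1)
  expect_lt(mae(y, predict(bundle, X)), sd(y))
  # constant target: MAE 0 for every family
  yc <- rep(10, n)
  for (fam in c("rf", "svm", "ann")) {
    params <- switch(fam, rf = list(n_estimators = 50),
                     svm = list(epsilon = 0.01, gamma = 0.1),
                     ann = list(size = 4, maxit = 50))
    b <- train_final(fam, params, X, yc, seed = 1)
    expect_lt(mae(yc, predict(b, X)), 0.2)
  }
  # seeded determinism of the forest
  b1 <- train_final("rf", list(n_estimators = 100), X, y, seed = 9)
  b2 <- train_final("rf", list(n_estimators = 100), X, y, seed = 9)
  expect_identical(predict(b1, X), predict(b2, X))
  expect_error(train_final("rf", list(), dplyr::mutate(X, f1 = Inf), y),
               "finite")
})

test_that("importances are normalized, ranked, and RF-only", {
  set.seed(8)
  n <- 300
  X <- tibble::tibble(big = rnorm(n), small = rnorm(n), null = rnorm(n))
  y <- 5 * X$big + 0.5 * X$small + rnorm(n, sd = 0.5)
  b <- train_final("rf", list(n_estimators = 200), X, y, seed = 1)
  imp <- feature_importance_rank(b)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_true(all(imp$weight >= 0))
  expect_equal(imp$feature[1], "big")
  expect_equal(imp$rank, 1:3)
  bs <- train_final("svm", list(epsilon = 0.1, gamma = 0.1), X, y)
  expect_error(feature_importance_rank(bs), "random-forest")
  # single feature gets weight 1
  b1 <- train_final("rf", list(n_estimators = 50),
                    X[, "big", drop = FALSE], y, seed = 1)
  expect_equal(feature_importance_rank(b1)$weight, 1)
})

test_that("evaluation reports residuals, MAE and 2-degree bins consistently", {
  set.seed(9)
  X <- tibble::tibble(x = rnorm(60))
  y <- 40 + 10 * X$x
  b <- train_final("rf", list(n_estimators = 100), X, y, seed = 2)
  ev <- evaluate_model(b, X, y)
  expect_equal(ev$mae, mean(abs(ev$residuals)))
  expect_equal(sum(ev$bins$count), ev$n)
  expect_equal(unique(round(ev$bins$bin_hi - ev$bins$bin_lo, 9)), 2)
  # batch prediction through predict_final_cobb reproduces the same MAE
  preds <- predict_final_cobb(b, X)
  expect_equal(mae(y, preds$.pred), ev$mae)
})

test_that("compare_models returns one finite row per family, seeded", {
  coh <- generate_cohort(n = 120, seed = 21)
  enc <- encode_cohort(coh)
  X <- enc[, setdiff(names(enc), "final_major_cobb")]
  grids <- list(rf = list(n_estimators = 100, max_features = c(3, 7)),
                svm = list(epsilon = 1, gamma = c(0.1, 0.001)),
                ann = list(size = 8, decay = 0.1, maxit = 100))
  tab <- compare_models(X, enc$final_major_cobb,
                        families = c("rf", "svm"), grids = grids, seed = 4)
  expect_equal(tab$model, c("rf", "svm"))
  expect_true(all(is.finite(tab$cv_train_mae)))
  expect_true(all(is.finite(tab$test_mae)))
  tab2 <- compare_models(X, enc$final_major_cobb,
                         families = c("rf", "svm"), grids = grids, seed = 4)
  expect_identical(tab, tab2)
})

test_that("prediction warns on extrapolation and memorizes training rows", {
  coh <- generate_cohort(n = 100, seed = 31)
  enc <- encode_cohort(coh)
  X <- enc[, setdiff(names(enc), "final_major_cobb")]
  y <- enc$final_major_cobb
  b <- train_final("rf", list(n_estimators = 300, max_depth = 0,
                              min_samples_split = 2, min_samples_leaf = 1),
                   X, y, seed = 5)
  # a record identical to a training row predicts near that row's target
  p1 <- predict_final_cobb(b, X[7, ])
  expect_lt(abs(p1$.pred - y[7]), 5)
  expect_false(p1$out_of_range)
  # out-of-range initial Cobb triggers the extrapolation warning
  far <- X[7, ]
  far$initial_major_cobb_angle <- 150
  expect_warning(p2 <- predict_final_cobb(b, far), "training range")
  expect_true(p2$out_of_range)
})

test_that("model bundles round-trip through versioned serialization", {
  coh <- generate_cohort(n = 60, seed = 41)
  enc <- encode_cohort(coh)
  X <- enc[, setdiff(names(enc), "final_major_cobb")]
  b <- train_final("rf", list(n_estimators = 50), X, enc$final_major_cobb,
                   seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model_bundle(b, path)
  b2 <- load_model_bundle(path)
  expect_identical(predict(b2, X), predict(b, X))
  # index-map mismatch refuses to load
  raw <- readRDS(path)
  raw$index_map$column[1] <- "something_else"
  saveRDS(raw, path)
  expect_error(load_model_bundle(path), "index map")
})

test_that("tidiers expose traces, importances and evaluation summaries", {
  coh <- generate_cohort(n = 80, seed = 51)
  enc <- encode_cohort(coh)
  X <- enc[, setdiff(names(enc), "final_major_cobb")]
  y <- enc$final_major_cobb
  sel <- sbfs_select(X[, 1:4], y, model_factory = lm_factory(), seed = 1)
  td <- tidy(sel)
  expect_true(sum(td$best) >= 1)
  expect_equal(glance(sel)$best_size, sel$best$n_features)
  b <- train_final("rf", list(n_estimators = 50), X, y, seed = 1)
  expect_equal(sum(tidy(b)$weight), 1, tolerance = 1e-9)
  expect_equal(glance(b)$family, "rf")
  aug <- augment(b, enc)
  expect_true(all(c(".pred", ".resid") %in% names(aug)))
  ev <- evaluate_model(b, X, y)
  expect_equal(glance(ev)$mae, ev$mae)
  expect_s3_class(autoplot(sel), "ggplot")
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
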