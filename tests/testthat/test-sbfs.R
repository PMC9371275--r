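test_that("cv_mae matches hand-computed fold arithmetic for a mean predictor", {
  # 6-row fixture, 2 folds; oracle computed fold-by-fold by hand below
  X <- tibble::tibble(x = rep(1, 6))
  y <- c(1, 2, 3, 10, 20, 30)
  folds <- c(1L, 1L, 1L, 2L, 2L, 2L)
  res <- cv_mae(X, y, subset = 0L, model_factory = mean_factory(),
                folds = folds)
  # fold 1 held out: train mean = 20, MAE = mean(|1-20|,|2-20|,|3-20|) = 18
  # fold 2 held out: train mean = 2,  MAE = mean(|10-2|,|20-2|,|30-2|) = 18
  expect_equal(res$fold_mae, c(18, 18))
  expect_equal(res$mean, 18)
  expect_equal(res$sd, 0)
})

test_that("cv_mae is deterministic under a seed and zero for a constant target", {
  X <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  y <- rep(5, 20)
  r1 <- cv_mae(X, y, model_factory = mean_factory(), seed = 7)
  r2 <- cv_mae(X, y, model_factory = mean_factory(), seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$mean, 0)
  expect_error(cv_mae(X, y, subset = 5L, model_factory = mean_factory()),
               "outside")
  expect_error(make_cv_folds(3, k = 5), "at least")
})

test_that("population SD over fold scores is recomputable from the folds", {
  set.seed(2)
  X <- tibble::tibble(x = rnorm(40))
  y <- 2 * X$x + rnorm(40)
  res <- cv_mae(X, y, model_factory = lm_factory(), seed = 3)
  expect_equal(res$mean, mean(res$fold_mae))
  expect_equal(res$sd, sqrt(mean((res$fold_mae - mean(res$fold_mae))^2)))
  expect_equal(res$k, 5)
})

test_that("single-feature selection returns that feature", {
  set.seed(1)
  X <- tibble::tibble(x0 = rnorm(30))
  y <- X$x0 + rnorm(30, sd = 0.1)
  sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = 1)
  expect_equal(nrow(sel$traces), 1)
  expect_equal(sel$best$feature_indices[[1]], 0L)
})

test_that("selection matches the exhaustive-search oracle on p = 3", {
  set.seed(1)
  n <- 300
  X <- tibble::tibble(x0 = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
  y <- 3 * X$x0 + rnorm(n, sd = 0.5)
  sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = 1)
  best <- sel$best$feature_indices[[1]]
  expect_true(0L %in% best)
  # the informative singleton beats the full set
  folds <- sel$folds
  expect_lt(cv_mae(X, y, 0L, lm_factory(), folds = folds)$mean,
            cv_mae(X, y, 0:2, lm_factory(), folds = folds)$mean)
  # exhaustive oracle over all 7 subsets, on the same paired folds
  subsets <- unlist(lapply(1:3, function(k) {
    utils::combn(0:2, k, simplify = FALSE)
  }), recursive = FALSE)
  oracle <- vapply(subsets, function(s) {
    cv_mae(X, y, s, lm_factory(), folds = folds)$mean
  }, numeric(1))
  oracle_best <- subsets[[which.min(oracle)]]
  expect_true(all(0L %in% oracle_best))
  expect_equal(sel$best$mean_mae, min(oracle), tolerance = 1e-12)
})

test_that("duplicated informative features: best within CV noise of exhaustive optimum", {
  set.seed(5)
  n <- 300
  x0 <- rnorm(n)
  X <- tibble::tibble(x0 = x0, x1 = x0 + rnorm(n, sd = 0.01),
                      x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * x0 + rnorm(n, sd = 0.5)
  sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = 2)
  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(0:3, k, simplify = FALSE)
  }), recursive = FALSE)
  oracle <- vapply(subsets, function(s) {
    cv_mae(X, y, s, lm_factory(), folds = sel$folds)$mean
  }, numeric(1))
  expect_lte(sel$best$mean_mae, min(oracle) + sel$best$sd_mae)
})

test_that("the best trace never loses to the full set and runs are seeded-identical", {
  set.seed(3)
  X <- tibble::as_tibble(matrix(rnorm(200 * 5), 200,
                                dimnames = list(NULL, paste0("f", 1:5))))
  y <- X$f1 - 2 * X$f3 + rnorm(200)
  s1 <- sbfs_select(X, y, model_factory = lm_factory(), seed = 11)
  s2 <- sbfs_select(X, y, model_factory = lm_factory(), seed = 11)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$best, s2$best)
  full <- s1$traces[s1$traces$n_features == 5, ]
  expect_lte(s1$best$mean_mae, full$mean_mae)
})

test_that("informative features are retained across seeded replicates", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    X <- tibble::tibble(x0 = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                        x3 = rnorm(n))
    y <- 3 * X$x0 + 2 * X$x1 + rnorm(n, sd = 0.5)
    sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = s)
    all(c(0L, 1L) %in% sel$best$feature_indices[[1]])
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("trace report ranks, formats and round-trips", {
  traces <- tibble::tibble(
    n_features = c(7L, 1L, 2L),
    feature_indices = list(c(0L, 1L, 3L, 7L, 9L, 12L, 14L), 9L, c(9L, 14L)),
    mean_mae = c(6.146, 6.807, 6.146),
    sd_mae = c(0.97, 0.79, 0.97),
    ci_bound = 1.2816 * c(0.97, 0.79, 0.97))
  rep <- trace_report(traces)
  # ascending MAE; equal MAE -> smaller subset first
  expect_equal(rep$n_features, c(2L, 7L, 1L))
  expect_equal(rep$feature_indices[2], "(0, 1, 3, 7, 9, 12, 14)")
  fmt <- format_trace_report(rep)
  expect_equal(fmt$mean_mae[2], "6.146")
  expect_equal(fmt$ci_bound[2], "1.24")   # 1.2816 * 0.97
  expect_equal(fmt$ci_bound[3], "1.01")   # 1.2816 * 0.79
  back <- parse_trace_report(fmt)
  expect_equal(back$mean_mae, rep$mean_mae)
  expect_equal(back$sd_mae, rep$sd_mae)
  expect_equal(back$n_features, rep$n_features)
})

test_that("memoization does not change results, only cost", {
  set.seed(4)
  X <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  y <- X$a + rnorm(100, sd = 0.3)
  sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = 5)
  # every recorded trace equals a fresh unmemoized evaluation on the folds
  for (i in seq_len(nrow(sel$traces))) {
    fresh <- cv_mae(X, y, sel$traces$feature_indices[[i]], lm_factory(),
                    folds = sel$folds)
    expect_equal(sel$traces$mean_mae[i], fresh$mean, tolerance = 1e-12)
  }
  expect_lte(sel$n_evaluations, 2^3)
})
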