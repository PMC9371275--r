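#' Mean absolute error
#'
#' `(1/n) * sum(|y - yhat|)`, the evaluation metric used throughout the
#' pipeline (degrees when the target is a Cobb angle).
#'
#' @param y Observed targets. @param yhat Predictions, same length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' mae(c(10, 20), c(12, 18))  # 2
mae <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop("y and yhat must have equal, nonzero length", call. = FALSE)
  }
  mean(abs(y - yhat))
}

#' Split a cohort into training and testing sets
#'
#' Seeded shuffle split; the test set receives `floor(test_fraction * n)`
#' rows and the training set the rest, disjoint and exhaustive.
#'
#' @param data A tibble (rows are patients).
#' @param test_fraction Fraction held out, in (0, 1); default 0.25.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
#' @examples
#' split_cohort(tibble::tibble(x = 1:8), test_fraction = 0.25, seed = 1)
split_cohort <- function(data, test_fraction = 0.25, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(data)
  if (n < 8) stop("need at least 8 rows to split", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(test_fraction * n)
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  list(train = data[train_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Default hyperparameter grids
#'
#' Deliberately coarse Cartesian grids spanning the tuning ranges of each
#' family: the random-forest grid covers trees 100-500, candidate features
#' per split 1-7, depth 10-50 and the two node-size controls 2-11 / 1-2;
#' the SVM grid covers tube widths 0-1000 and kernel widths 1e-4-1; the
#' neural-network grid covers hidden-layer size, weight decay and
#' optimizer iterations.
#'
#' @return Named list of grids (one named list of value vectors per
#'   family).
#' @export
default_grids <- function() {
  list(
    rf = list(n_estimators = c(100, 300, 500),
              max_features = c(1, 4, 7),
              max_depth = c(10, 30, 50),
              min_samples_split = c(2, 7, 11),
              min_samples_leaf = c(1, 2)),
    svm = list(epsilon = c(0, 1, 10, 100, 1000),
               gamma = c(1, 0.1, 0.001, 0.0001)),
    ann = list(size = c(8, 16),
               decay = c(0.01, 0.1),
               maxit = c(100, 200)))
}

family_factory <- function(family, params, seed = 1) {
  switch(family,
    rf = do.call(rf_factory, c(params, list(seed = seed))),
    svm = do.call(svm_factory, params),
    ann = do.call(ann_factory, c(params, list(seed = seed))),
    stop("unknown model family: ", family, call. = FALSE))
}

#' Exhaustive grid search under cross-validated MAE
#'
#' Scores every combination of the grid by seeded k-fold cross-validated
#' MAE and returns the argmin; ties go to the first combination in the
#' deterministic grid iteration order (`expand.grid` on the grid as
#' given). A combination on which the estimator fails scores `Inf` with a
#' warning rather than aborting the search.
#'
#' @param family `"rf"`, `"svm"` or `"ann"`.
#' @param grid Named list of candidate value vectors.
#' @param X,y Training features (numeric tibble) and target.
#' @param k Folds. @param seed Seed for the fold partition and seeded
#'   estimators.
#' @return List with `best_params` (named list), `cv` (the winning
#'   [cv_mae()] result) and `results` (tibble of all combinations with
#'   their scores).
#' @export
grid_search <- function(family, grid, X, y, k = 5, seed = 1) {
  stopifnot(length(grid) > 0, all(nzchar(names(grid))))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  folds <- make_cv_folds(length(y), k = k, seed = seed)
  cvs <- vector("list", nrow(combos))
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    params <- as.list(combos[i, , drop = FALSE])
    res <- tryCatch(
      cv_mae(X, y, model_factory = family_factory(family, params, seed),
             folds = folds),
      error = function(e) {
        warning("grid point ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    cvs[[i]] <<- res
    if (is.null(res)) Inf else res$mean
  }, numeric(1))
  best <- which.min(scores)
  results <- tibble::as_tibble(combos)
  results$cv_mae <- scores
  list(best_params = as.list(combos[best, , drop = FALSE]),
       cv = cvs[[best]], results = results)
}

#' Train a final progression model
#'
#' Fits the chosen family at fixed hyperparameters on the full training
#' matrix and wraps it in a model bundle that remembers its feature
#' indexing, preprocessing policy, seed and per-feature training ranges
#' (used to warn about extrapolation at prediction time).
#'
#' @param family `"rf"`, `"svm"` or `"ann"`.
#' @param params Named list of hyperparameters for the family.
#' @param X Numeric feature tibble (training). @param y Numeric target.
#' @param seed Integer seed. @param cv Optional [cv_mae()] result from
#'   tuning, stored as the bundle's training CV MAE.
#' @return An object of class `cobb_model`.
#' @export
train_final <- function(family, params, X, y, seed = 1, cv = NULL) {
  X <- tibble::as_tibble(X)
  if (!all(vapply(X, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(X)))) {
    stop("features must be numeric and finite", call. = FALSE)
  }
  fit <- family_factory(family, params, seed)(X, y)
  ft <- feature_table()
  structure(list(
    family = family,
    fit = fit,
    params = params,
    feature_names = names(X),
    feature_indices = ft$index[match(names(X), ft$column)],
    train_range = lapply(X, range),
    n_train = nrow(X),
    seed = seed,
    cv_train_mae = if (is.null(cv)) NA_real_ else cv$mean,
    cv = cv), class = "cobb_model")
}

#' @export
print.cobb_model <- function(x, ...) {
  cat("<cobb_model> family: ", x$family, ", ", length(x$feature_names),
      " features, n_train = ", x$n_train, "\n", sep = "")
  if (is.finite(x$cv_train_mae)) {
    cat(sprintf("training CV MAE: %.3f\n", x$cv_train_mae))
  }
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.cobb_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stats::predict(object$fit,
                 newdata[, object$feature_names, drop = FALSE])
}

#' Feature-importance ranking of a random-forest bundle
#'
#' Impurity-based importances of the fitted forest, normalized to sum to
#' one and sorted descending. Only defined for random-forest bundles.
#'
#' @param bundle A `cobb_model` with `family = "rf"`.
#' @return Tibble with `rank`, `feature`, `index` (the model feature index
#'   when the feature is one of the 15 canonical inputs) and `weight`.
#' @export
feature_importance_rank <- function(bundle) {
  stopifnot(inherits(bundle, "cobb_model"))
  if (bundle$family != "rf") {
    stop("feature importances are only available for random-forest models",
         call. = FALSE)
  }
  imp <- ranger::importance(bundle$fit$fit)
  w <- imp / sum(imp)
  out <- tibble::tibble(feature = names(w),
                        index = bundle$feature_indices[
                          match(names(w), bundle$feature_names)],
                        weight = unname(w))
  out <- dplyr::arrange(out, dplyr::desc(.data$weight))
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "feature", "index", "weight")]
}

#' Evaluate a model bundle on held-out data
#'
#' Computes per-patient residuals (prediction minus observation), the MAE
#' and a residual histogram in fixed-width bins.
#'
#' @param bundle A `cobb_model`. @param X_test,y_test Held-out features
#'   and targets. @param bin_width Histogram bin width in degrees
#'   (default 2).
#' @return An object of class `cobb_evaluation`: list with `residuals`,
#'   `mae`, `n`, `bins` (tibble of `bin_lo`, `bin_hi`, `count`).
#' @export
evaluate_model <- function(bundle, X_test, y_test, bin_width = 2) {
  pred <- stats::predict(bundle, X_test)
  resid <- pred - y_test
  lo <- floor(min(resid) / bin_width) * bin_width
  hi <- ceiling(max(resid) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- table(cut(resid, breaks = breaks, include.lowest = TRUE,
                      right = FALSE))
  structure(list(residuals = resid, mae = mae(y_test, pred),
                 n = length(resid),
                 bins = tibble::tibble(bin_lo = breaks[-length(breaks)],
                                       bin_hi = breaks[-1],
                                       count = as.integer(counts))),
            class = "cobb_evaluation")
}

#' @export
print.cobb_evaluation <- function(x, ...) {
  cat(sprintf("<cobb_evaluation> n = %d, MAE = %.3f degrees\n", x$n, x$mae))
  invisible(x)
}

#' Tune, train and compare model families
#'
#' For each requested family: grid search on the training split, final
#' training at the selected hyperparameters, and held-out evaluation.
#' A family whose tuning or training fails is reported as a row of NAs
#' with a warning rather than aborting the comparison.
#'
#' @param X,y Encoded feature tibble and target for the whole cohort.
#' @param families Character vector among `"rf"`, `"svm"`, `"ann"`.
#' @param grids Named list of grids, as [default_grids()].
#' @param test_fraction Held-out fraction. @param k CV folds.
#' @param seed Integer seed (drives the split, the fold partitions and
#'   the seeded estimators).
#' @return Tibble with one row per family: `model`, `cv_train_mae`,
#'   `test_mae`.
#' @export
compare_models <- function(X, y, families = c("rf", "svm", "ann"),
                           grids = default_grids(), test_fraction = 0.25,
                           k = 5, seed = 1) {
  dat <- tibble::as_tibble(X)
  dat$.outcome <- y
  parts <- split_cohort(dat, test_fraction = test_fraction, seed = seed)
  X_tr <- parts$train[, setdiff(names(dat), ".outcome"), drop = FALSE]
  y_tr <- parts$train$.outcome
  X_te <- parts$test[, setdiff(names(dat), ".outcome"), drop = FALSE]
  y_te <- parts$test$.outcome
  purrr::map_dfr(families, function(fam) {
    row <- tryCatch({
      gs <- grid_search(fam, grids[[fam]], X_tr, y_tr, k = k, seed = seed)
      bundle <- train_final(fam, gs$best_params, X_tr, y_tr, seed = seed,
                            cv = gs$cv)
      tibble::tibble(model = fam, cv_train_mae = gs$cv$mean,
                     test_mae = evaluate_model(bundle, X_te, y_te)$mae)
    }, error = function(e) {
      warning("family ", fam, " failed: ", conditionMessage(e),
              call. = FALSE)
      tibble::tibble(model = fam, cv_train_mae = NA_real_,
                     test_mae = NA_real_)
    })
    row
  })
}

#' Predict the final major Cobb angle for new patients
#'
#' Encodes raw records if needed, restricts to the bundle's features,
#' predicts, and annotates each prediction with the training-CV MAE band.
#' Because forests cannot extrapolate beyond their training support, a
#' warning lists any feature value outside the training range.
#'
#' @param bundle A `cobb_model`.
#' @param records Raw cohort tibble (human-readable) or an
#'   [encode_cohort()] matrix.
#' @return Tibble with `.pred`, `.pred_lower`, `.pred_upper` (prediction
#'   +/- training CV MAE) and `out_of_range` (logical).
#' @export
predict_final_cobb <- function(bundle, records) {
  records <- tibble::as_tibble(records)
  raw <- "risser_plus_stage" %in% names(records) &&
    !is.numeric(records$risser_plus_stage)
  encoded <- if (raw) encode_cohort(records) else records
  missing_cols <- setdiff(bundle$feature_names, names(encoded))
  if (length(missing_cols) > 0) {
    stop("records lack feature column(s) the model was trained on: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  oor <- rep(FALSE, nrow(encoded))
  oor_features <- character()
  for (nm in bundle$feature_names) {
    rng <- bundle$train_range[[nm]]
    bad <- encoded[[nm]] < rng[1] | encoded[[nm]] > rng[2]
    if (any(bad)) oor_features <- c(oor_features, nm)
    oor <- oor | bad
  }
  if (length(oor_features) > 0) {
    warning("feature value(s) outside the training range (the model ",
            "cannot extrapolate): ", paste(oor_features, collapse = ", "),
            call. = FALSE)
  }
  pred <- stats::predict(bundle, encoded)
  band <- if (is.finite(bundle$cv_train_mae)) bundle$cv_train_mae else NA_real_
  tibble::tibble(.pred = pred, .pred_lower = pred - band,
                 .pred_upper = pred + band, out_of_range = oor)
}

bundle_format_version <- "1"

#' Save / load a model bundle
#'
#' Versioned serialization of a `cobb_model`. Loading refuses bundles
#' whose format version or feature-index map does not match the current
#' package, so stale bundles cannot silently mis-index features.
#'
#' @param bundle A `cobb_model`. @param path File path.
#' @return `save_model_bundle()` the path invisibly;
#'   `load_model_bundle()` the bundle.
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "cobb_model"))
  saveRDS(list(format_version = bundle_format_version,
               package_version = as.character(utils::packageVersion("curveprog")),
               index_map = feature_table()[, c("index", "column")],
               bundle = bundle),
          path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, bundle_format_version)) {
    stop("bundle format version ", obj$format_version,
         " does not match this package (", bundle_format_version, ")",
         call. = FALSE)
  }
  current <- feature_table()[, c("index", "column")]
  if (!isTRUE(all.equal(as.data.frame(obj$index_map),
                        as.data.frame(current)))) {
    stop("bundle feature-index map does not match this package; ",
         "refusing to load", call. = FALSE)
  }
  obj$bundle
}
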