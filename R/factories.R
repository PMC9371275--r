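#' Model factories
#'
#' A model factory is a zero-setup recipe: a function `f(X, y)` that fits a
#' fresh regressor on a numeric feature tibble `X` and target `y` and
#' returns a fitted object that [predict()] maps back to a numeric vector.
#' Factories are what [cv_mae()], [sbfs_select()] and [grid_search()]
#' consume, so the selection machinery is agnostic to the learner.
#'
#' @name model-factories
NULL

new_cp_fit <- function(fit, predict_fn) {
  structure(list(fit = fit, predict_fn = predict_fn), class = "cp_fit")
}

#' @export
predict.cp_fit <- function(object, newdata, ...) {
  as.numeric(object$predict_fn(newdata))
}

#' Random-forest factory
#'
#' Ensemble regression trees (delegated to \pkg{ranger}, single-threaded
#' and seeded for reproducibility). Hyperparameter names follow the common
#' tabular-ML surface: `n_estimators` (trees), `max_features` (candidate
#' features per split), `max_depth`, `min_samples_split` (minimum node size
#' eligible for splitting), `min_samples_leaf` (minimum terminal node
#' size).
#'
#' @param n_estimators,max_features,max_depth,min_samples_split,min_samples_leaf
#'   Forest hyperparameters. `max_features = NULL` uses the engine default
#'   (square root of the feature count, capped at the feature count
#'   otherwise).
#' @param seed Integer seed baked into every fit the factory produces.
#' @param importance Impurity-based by default; `"permutation"` available.
#' @return A model factory.
#' @export
#' @family model factories
rf_factory <- function(n_estimators = 100, max_features = NULL,
                       max_depth = NULL, min_samples_split = 5,
                       min_samples_leaf = 1, seed = 1,
                       importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  function(X, y) {
    dat <- as.data.frame(X)
    dat$.outcome <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".outcome", data = dat,
      num.trees = n_estimators,
      mtry = if (is.null(max_features)) NULL else min(max_features, ncol(X)),
      max.depth = if (is.null(max_depth)) 0 else max_depth,
      min.node.size = min_samples_split,
      min.bucket = min_samples_leaf,
      importance = importance,
      seed = seed, num.threads = 1, verbose = FALSE)
    new_cp_fit(fit, function(newdata) {
      stats::predict(fit, data = as.data.frame(newdata),
                     num.threads = 1)$predictions
    })
  }
}

#' Linear-model factory
#'
#' Ordinary least squares; fast, and the natural reference learner on the
#' linear synthetic cohorts.
#'
#' @return A model factory.
#' @export
#' @family model factories
lm_factory <- function() {
  function(X, y) {
    dat <- as.data.frame(X)
    dat$.outcome <- y
    fit <- stats::lm(.outcome ~ ., data = dat)
    new_cp_fit(fit, function(newdata) {
      unname(stats::predict(fit, newdata = as.data.frame(newdata)))
    })
  }
}

#' Mean-predictor factory
#'
#' Predicts the training mean everywhere; the textbook baseline used in
#' hand-checkable cross-validation fixtures.
#'
#' @return A model factory.
#' @export
#' @family model factories
mean_factory <- function() {
  function(X, y) {
    m <- mean(y)
    new_cp_fit(m, function(newdata) rep(m, nrow(newdata)))
  }
}

# One-hot expand nominal columns and centre/scale the rest. Fit on the
# training matrix; the returned transform is applied to any new matrix.
# Distance-based learners (SVM, neural network) get this; trees see the
# plain integer-coded matrix so the feature-index bookkeeping stays intact.
make_preprocessor <- function(X, nominal = NULL) {
  if (is.null(nominal)) {
    nominal <- intersect(names(X), c("lenke_type", "gender", "brace_status"))
  }
  nominal <- intersect(nominal, names(X))
  levels_map <- lapply(X[nominal], function(col) sort(unique(col)))
  continuous <- setdiff(names(X), nominal)
  centre <- vapply(X[continuous], mean, numeric(1))
  scale_ <- vapply(X[continuous], stats::sd, numeric(1))
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  transform <- function(newX) {
    parts <- list()
    if (length(continuous) > 0) {
      parts$cont <- sweep(sweep(as.matrix(newX[, continuous, drop = FALSE]),
                                2, centre), 2, scale_, "/")
    }
    for (nm in nominal) {
      lv <- levels_map[[nm]]
      oh <- outer(newX[[nm]], lv, `==`) * 1
      colnames(oh) <- paste0(nm, "_", lv)
      parts[[nm]] <- oh
    }
    do.call(cbind, parts)
  }
  list(transform = transform, nominal = nominal, continuous = continuous)
}

#' Support-vector-machine factory
#'
#' Epsilon-regression SVM with a radial-basis kernel (via \pkg{e1071}).
#' Nominal features are one-hot expanded and continuous features
#' standardized inside the adapter, so the shared integer-coded feature
#' matrix is untouched. An `epsilon` of 0 is mapped to a small positive
#' tube (1e-3), since a zero-width tube is degenerate.
#'
#' @param epsilon Tube width. @param gamma RBF kernel width.
#' @param cost Regularization constant, default 1.
#' @return A model factory.
#' @export
#' @family model factories
svm_factory <- function(epsilon = 0.1, gamma = 0.1, cost = 1) {
  if (epsilon <= 0) epsilon <- 1e-3
  function(X, y) {
    pp <- make_preprocessor(X)
    Xt <- pp$transform(X)
    fit <- tryCatch(
      e1071::svm(x = Xt, y = y, type = "eps-regression",
                 kernel = "radial", cost = cost, epsilon = epsilon,
                 gamma = gamma, scale = FALSE),
      error = function(e) {
        if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
        else stop(e)
      })
    if (is.null(fit) || fit$tot.nSV == 0) {
      # every residual inside the tube (e.g. a constant target): the
      # empty model predicts the training mean
      m <- mean(y)
      return(new_cp_fit(m, function(newdata) rep(m, nrow(newdata))))
    }
    new_cp_fit(fit, function(newdata) {
      stats::predict(fit, pp$transform(newdata))
    })
  }
}

#' Neural-network factory
#'
#' Single-hidden-layer feed-forward network (via \pkg{nnet}) with a linear
#' output unit, seeded initialization, standardized inputs and a
#' standardized target (rescaled back at prediction). The tunable surface
#' is `size` (hidden units), `decay` (L2 penalty) and `maxit`
#' (optimizer iterations).
#'
#' @param size Hidden units. @param decay Weight decay. @param maxit
#'   Maximum optimizer iterations.
#' @param seed Seed for the initial weights.
#' @return A model factory.
#' @export
#' @family model factories
ann_factory <- function(size = 16, decay = 0.01, maxit = 200, seed = 1) {
  function(X, y) {
    pp <- make_preprocessor(X)
    Xt <- pp$transform(X)
    y_c <- mean(y)
    y_s <- stats::sd(y)
    if (!is.finite(y_s) || y_s == 0) y_s <- 1
    set.seed(seed)
    fit <- nnet::nnet(x = Xt, y = (y - y_c) / y_s, size = size,
                      decay = decay, maxit = maxit, linout = TRUE,
                      trace = FALSE)
    new_cp_fit(fit, function(newdata) {
      stats::predict(fit, pp$transform(newdata))[, 1] * y_s + y_c
    })
  }
}
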