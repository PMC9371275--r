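#' Seeded k-fold partition
#'
#' Shuffles the row indices with the given seed and deals them into k
#' folds of near-equal size. The same (n, k, seed) always yields the same
#' partition, so subset comparisons that share a partition are paired.
#'
#' @param n Number of rows. @param k Number of folds. @param seed Integer
#'   seed.
#' @return Integer vector of fold labels (1..k), one per row.
#' @export
make_cv_folds <- function(n, k = 5, seed = 1) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  if (n < k) stop("n (", n, ") must be at least the number of folds (", k,
                  ")", call. = FALSE)
  set.seed(seed)
  shuffled <- sample.int(n)
  folds <- integer(n)
  folds[shuffled] <- rep_len(seq_len(k), n)
  folds
}

#' Cross-validated mean absolute error of a feature subset
#'
#' For each fold, fits a fresh model from the factory on the remaining
#' folds restricted to `subset`, predicts the held-out fold, and records
#' the fold MAE. Deterministic given the fold partition (pass `folds` to
#' pair evaluations, or `seed` to build one).
#'
#' @param X Numeric feature tibble/data frame. @param y Numeric target.
#' @param subset 0-based feature indices into the columns of `X`
#'   (`NULL` = all features).
#' @param model_factory A [model factory][model-factories].
#' @param k Number of folds (default 5). @param seed Seed used when
#'   `folds` is not supplied.
#' @param folds Optional precomputed fold labels from [make_cv_folds()].
#' @return An object of class `cv_mae`: list with `fold_mae` (k values),
#'   `mean`, `sd` (population SD over folds) and `k`.
#' @export
#' @examples
#' X <- tibble::tibble(x0 = rnorm(30), x1 = rnorm(30))
#' cv_mae(X, X$x0 * 2 + rnorm(30, sd = .1), subset = 0L,
#'        model_factory = lm_factory(), seed = 1)
cv_mae <- function(X, y, subset = NULL, model_factory, k = 5, seed = 1,
                   folds = NULL) {
  X <- tibble::as_tibble(X)
  p <- ncol(X)
  if (is.null(subset)) subset <- seq_len(p) - 1L
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("empty feature subset", call. = FALSE)
  if (any(subset < 0 | subset >= p)) {
    stop("feature subset references index outside 0..", p - 1, call. = FALSE)
  }
  if (is.null(folds)) folds <- make_cv_folds(length(y), k = k, seed = seed)
  k <- max(folds)
  Xs <- X[, subset + 1L, drop = FALSE]
  fold_mae <- vapply(seq_len(k), function(f) {
    test <- folds == f
    fit <- model_factory(Xs[!test, , drop = FALSE], y[!test])
    mae(y[test], stats::predict(fit, Xs[test, , drop = FALSE]))
  }, numeric(1))
  m <- mean(fold_mae)
  structure(list(fold_mae = fold_mae, mean = m,
                 sd = sqrt(mean((fold_mae - m)^2)), k = k),
            class = "cv_mae")
}

#' @export
print.cv_mae <- function(x, ...) {
  cat(sprintf("<cv_mae> %d-fold: mean %.3f (sd %.3f)\n", x$k, x$mean, x$sd))
  invisible(x)
}

subset_key <- function(s) paste(sort(s), collapse = ",")

#' Sequential backward floating selection under cross-validated MAE
#'
#' Starts from the full feature set and repeatedly excludes the feature
#' whose removal minimizes the k-fold cross-validated MAE; after every
#' exclusion, a floating step conditionally re-includes previously
#' excluded features for as long as some inclusion strictly improves on
#' the best subset recorded at the target size. Every accepted working
#' set is recorded as a trace; the best subset is the trace with minimal
#' mean MAE (ties: smaller subset, then lexicographically smallest index
#' set). All evaluations share one seeded fold partition and are
#' memoized, so each subset is scored at most once.
#'
#' @inheritParams cv_mae
#' @param min_size Smallest subset size to descend to (default 1).
#' @param ci_multiplier Multiplier applied to the fold-score SD to form
#'   the reported confidence bound column (default 1.2816).
#' @return An object of class `cobb_sbfs`: list with `best` (one-row
#'   trace tibble), `traces` (all recorded traces), `folds`, `k`, `seed`,
#'   `ci_multiplier`, `n_evaluations`.
#' @export
#' @examples
#' set.seed(1)
#' X <- tibble::tibble(x0 = rnorm(60), x1 = rnorm(60), x2 = rnorm(60))
#' y <- 3 * X$x0 + rnorm(60, sd = 0.5)
#' sel <- sbfs_select(X, y, model_factory = lm_factory(), seed = 1)
#' sel$best
sbfs_select <- function(X, y, model_factory = rf_factory(), k = 5, seed = 1,
                        min_size = 1, ci_multiplier = 1.2816) {
  X <- tibble::as_tibble(X)
  p <- ncol(X)
  if (p < 1) stop("X must have at least one feature", call. = FALSE)
  folds <- make_cv_folds(length(y), k = k, seed = seed)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(s) {
    key <- subset_key(s)
    if (exists(key, envir = cache, inherits = FALSE)) return(cache[[key]])
    res <- tryCatch(
      cv_mae(X, y, subset = s, model_factory = model_factory, folds = folds),
      error = function(e) {
        stop("model factory failed on subset {", key, "}: ",
             conditionMessage(e), call. = FALSE)
      })
    n_eval <<- n_eval + 1L
    cache[[key]] <- res
    res
  }

  traces <- list()
  recorded <- character()
  record <- function(s) {
    key <- subset_key(s)
    if (key %in% recorded) return(invisible())
    recorded <<- c(recorded, key)
    res <- score(s)
    traces[[length(traces) + 1L]] <<- tibble::tibble(
      n_features = length(s),
      feature_indices = list(sort(as.integer(s))),
      mean_mae = res$mean, sd_mae = res$sd,
      ci_bound = ci_multiplier * res$sd)
    invisible()
  }

  best_at_size <- rep(Inf, p)
  note_size <- function(s) {
    sz <- length(s)
    m <- score(s)$mean
    if (m < best_at_size[sz]) best_at_size[sz] <<- m
  }

  S <- seq_len(p) - 1L
  record(S); note_size(S)
  guard <- 0L
  while (length(S) > min_size) {
    guard <- guard + 1L
    if (guard > 100L * p) {
      warning("floating selection stopped by iteration guard", call. = FALSE)
      break
    }
    # exclusion: drop the feature whose removal minimizes CV MAE
    cand <- sort(S)
    removal_mae <- vapply(cand, function(f) score(setdiff(S, f))$mean,
                          numeric(1))
    S <- setdiff(S, cand[which.min(removal_mae)])
    record(S); note_size(S)
    # floating inclusion: re-add while it strictly beats the best
    # recorded subset of the target size
    while (length(S) < p) {
      excl <- sort(setdiff(seq_len(p) - 1L, S))
      add_mae <- vapply(excl, function(g) score(union(S, g))$mean, numeric(1))
      g_best <- which.min(add_mae)
      if (add_mae[g_best] < best_at_size[length(S) + 1L]) {
        S <- sort(union(S, excl[g_best]))
        record(S); note_size(S)
      } else {
        break
      }
    }
  }

  traces <- dplyr::bind_rows(traces)
  # best: min MAE, ties -> smaller size, then lexicographically smallest set
  key_str <- vapply(traces$feature_indices, function(s) {
    paste(sprintf("%02d", s), collapse = ",")
  }, character(1))
  ord <- order(traces$mean_mae, traces$n_features, key_str)
  structure(list(best = traces[ord[1], , drop = FALSE],
                 traces = traces, folds = folds, k = max(folds), seed = seed,
                 ci_multiplier = ci_multiplier, n_evaluations = n_eval),
            class = "cobb_sbfs")
}

#' @export
print.cobb_sbfs <- function(x, ...) {
  cat("<cobb_sbfs> ", nrow(x$traces), " recorded subsets (",
      x$n_evaluations, " CV evaluations, ", x$k, "-fold)\n", sep = "")
  cat("best subset: (",
      paste(x$best$feature_indices[[1]], collapse = ", "),
      ")  mean MAE ", sprintf("%.3f", x$best$mean_mae), "\n", sep = "")
  invisible(x)
}

#' Ranked subset-trace table
#'
#' Arranges the recorded SBFS traces by ascending cross-validated mean
#' MAE (ties: smaller subsets first), with the feature index set rendered
#' as a tuple string and the confidence bound as `ci_multiplier * SD`.
#'
#' @param x A `cobb_sbfs` object, or a traces tibble.
#' @return Tibble with columns `n_features`, `feature_indices` (string),
#'   `mean_mae`, `sd_mae`, `ci_bound`.
#' @export
trace_report <- function(x) {
  traces <- if (inherits(x, "cobb_sbfs")) x$traces else x
  stopifnot(nrow(traces) >= 1)
  out <- dplyr::arrange(traces, .data$mean_mae, .data$n_features)
  out$feature_indices <- vapply(out$feature_indices, function(s) {
    if (length(s) == 1) as.character(s)
    else paste0("(", paste(s, collapse = ", "), ")")
  }, character(1))
  tibble::as_tibble(out)
}

#' Render / parse a trace report at table precision
#'
#' `format_trace_report()` renders the numeric columns the way ranked
#' selection tables are printed (MAE to 3 decimals, SD and CI bound to 2);
#' `parse_trace_report()` inverts it.
#'
#' @param report A [trace_report()] tibble (numeric) or its formatted
#'   counterpart.
#' @return A tibble.
#' @export
format_trace_report <- function(report) {
  tibble::tibble(
    n_features = as.character(report$n_features),
    feature_indices = report$feature_indices,
    mean_mae = sprintf("%.3f", report$mean_mae),
    sd_mae = sprintf("%.2f", report$sd_mae),
    ci_bound = sprintf("%.2f", report$ci_bound))
}

#' @rdname format_trace_report
#' @export
parse_trace_report <- function(report) {
  tibble::tibble(
    n_features = as.integer(report$n_features),
    feature_indices = report$feature_indices,
    mean_mae = as.numeric(report$mean_mae),
    sd_mae = as.numeric(report$sd_mae),
    ci_bound = as.numeric(report$ci_bound))
}
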