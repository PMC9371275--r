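#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an SBFS result
#'
#' One row per recorded subset trace, ranked by ascending cross-validated
#' mean MAE, with the index set as a list-column.
#'
#' @param x A [sbfs_select()] result. @param ... Unused.
#' @return A tibble: `n_features`, `feature_indices`, `mean_mae`,
#'   `sd_mae`, `ci_bound`, `best`.
#' @export
tidy.cobb_sbfs <- function(x, ...) {
  out <- dplyr::arrange(x$traces, .data$mean_mae, .data$n_features)
  out$best <- purrr::map_lgl(out$feature_indices, identical,
                             x$best$feature_indices[[1]])
  tibble::as_tibble(out)
}

#' Glance at an SBFS result
#'
#' @param x A [sbfs_select()] result. @param ... Unused.
#' @return One-row tibble: best subset size and score, trace and
#'   evaluation counts, folds, seed.
#' @export
glance.cobb_sbfs <- function(x, ...) {
  tibble::tibble(
    best_size = x$best$n_features,
    best_mean_mae = x$best$mean_mae,
    best_sd_mae = x$best$sd_mae,
    n_traces = nrow(x$traces),
    n_evaluations = x$n_evaluations,
    k = x$k, seed = x$seed)
}

#' Tidy a fitted progression model
#'
#' For random forests, the importance ranking ([feature_importance_rank()]);
#' for other families, the feature list.
#'
#' @param x A `cobb_model`. @param ... Unused.
#' @return A tibble.
#' @export
tidy.cobb_model <- function(x, ...) {
  if (x$family == "rf") return(feature_importance_rank(x))
  tibble::tibble(feature = x$feature_names, index = x$feature_indices)
}

#' Glance at a fitted progression model
#'
#' @param x A `cobb_model`. @param ... Unused.
#' @return One-row tibble: family, feature count, training size, training
#'   CV MAE and the hyperparameters as a string.
#' @export
glance.cobb_model <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_features = length(x$feature_names),
    n_train = x$n_train,
    cv_train_mae = x$cv_train_mae,
    hyperparameters = paste(names(x$params), unlist(x$params),
                            sep = "=", collapse = ", "))
}

#' Augment data with model predictions
#'
#' @param x A `cobb_model`.
#' @param data Encoded feature tibble (optionally with
#'   `final_major_cobb`).
#' @param ... Unused.
#' @return `data` with `.pred` (and `.resid` when the target is present).
#' @export
augment.cobb_model <- function(x, data, ...) {
  data <- tibble::as_tibble(data)
  data$.pred <- stats::predict(x, data)
  if ("final_major_cobb" %in% names(data)) {
    data$.resid <- data$.pred - data$final_major_cobb
  }
  data
}

#' Tidy an evaluation report
#'
#' @param x A [evaluate_model()] result. @param ... Unused.
#' @return Tibble of residuals, one row per held-out patient.
#' @export
tidy.cobb_evaluation <- function(x, ...) {
  tibble::tibble(residual = x$residuals)
}

#' Glance at an evaluation report
#'
#' @param x A [evaluate_model()] result. @param ... Unused.
#' @return One-row tibble: `n`, `mae`, and the residual mean and SD.
#' @export
glance.cobb_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, mae = x$mae,
                 residual_mean = mean(x$residuals),
                 residual_sd = stats::sd(x$residuals))
}
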