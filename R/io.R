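#' Read a landmark CSV
#'
#' The documented long format: UTF-8, comma-separated, mandatory header
#' `patient_id, visit, view, level, corner, x, y`, one row per vertebral
#' corner. The table is validated on read ([validate_landmarks()]); all
#' violations are reported together with their location.
#'
#' @param path CSV path.
#' @return A validated landmark tibble.
#' @export
read_landmarks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          visit = readr::col_integer(),
                          view = readr::col_character(),
                          level = readr::col_character(),
                          corner = readr::col_character(),
                          x = readr::col_double(),
                          y = readr::col_double()))
  missing <- setdiff(landmark_cols, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_landmarks(df)
  tibble::as_tibble(df)
}

#' Write a landmark table to CSV
#'
#' Inverse of [read_landmarks()]; `read_landmarks(write_landmarks(x, f))`
#' is the identity on canonical (validated) tables.
#'
#' @param landmarks A landmark tibble. @param path Output path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  validate_landmarks(landmarks)
  readr::write_csv(landmarks[, landmark_cols], path, progress = FALSE)
  invisible(path)
}

#' Write curve measurements to CSV
#'
#' One row per detected curve, as produced by [measure_all()].
#'
#' @param measures A [measure_all()] tibble. @param path Output path.
#' @return The path, invisibly.
#' @export
write_curve_measures <- function(measures, path) {
  readr::write_csv(measures, path, progress = FALSE)
  invisible(path)
}

cohort_required_cols <- function() c(feature_table()$column, "final_major_cobb")

#' Read and validate a cohort CSV
#'
#' One row per patient; columns are the canonical feature names (see
#' [feature_table()]) plus `final_major_cobb`; Risser grades as strings
#' from the eight-symbol vocabulary. Rows violating the record invariants
#' are rejected with reasons - all of a file's problems are collected and
#' reported together, and the rejected-row count is messaged. Unknown or
#' missing columns and empty files are errors.
#'
#' @param path CSV path.
#' @param target_required Is `final_major_cobb` mandatory (default TRUE)?
#' @return A validated raw cohort tibble; rejected rows are dropped and
#'   described in attribute `rejected` (tibble of row/reason).
#' @export
read_cohort <- function(path, target_required = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop(path, ": empty cohort file", call. = FALSE)
  required <- feature_table()$column
  if (target_required) required <- c(required, "final_major_cobb")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), c("patient_id", cohort_required_cols()))
  if (length(unknown) > 0) {
    stop(path, ": unknown column(s) ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(df, target_required = target_required)
}

#' Validate cohort records
#'
#' Applies the record invariants: no missing fields, time span positive
#' and equal to the age difference (to rounding), flexibility in
#' \[0, 100\], at least 2 levels involved, finite angles, vocabularies
#' (Risser grades, gender, brace status, Lenke 1-6, apex T1-L5). Invalid
#' rows are dropped with reasons collected per file, not fail-fast.
#'
#' @inheritParams read_cohort
#' @param cohort A raw cohort tibble.
#' @return The surviving rows, with attribute `rejected`.
#' @export
validate_cohort <- function(cohort, target_required = TRUE) {
  n <- nrow(cohort)
  reasons <- vector("list", n)
  add <- function(rows, why) {
    for (i in which(rows)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  req <- feature_table()$column
  if (target_required) req <- c(req, "final_major_cobb")
  add(rowSums(is.na(cohort[, req])) > 0, "missing field")
  risser_ok <- trimws(as.character(cohort$risser_plus_stage)) %in%
    risser_vocabulary
  add(!risser_ok, "unknown Risser grade")
  add(!toupper(substr(trimws(cohort$gender), 1, 1)) %in% c("F", "M"),
      "unknown gender")
  add(!tolower(gsub("[ _]", "-", trimws(cohort$brace_status))) %in%
        names(brace_codes), "unknown brace status")
  add(!cohort$lenke_type %in% 1:6, "Lenke type outside 1..6")
  add(!trimws(cohort$apex_location) %in% spinal_levels(),
      "apex level outside T1..L5")
  ts <- cohort$time_span
  add(!is.na(ts) & ts <= 0, "non-positive time span")
  span_mismatch <- abs(cohort$age_at_last_visit - cohort$age_at_first_visit -
                         ts) > 0.06
  add(!is.na(span_mismatch) & span_mismatch,
      "age at last visit does not equal age at first visit + time span")
  add(!is.na(cohort$flexibility) &
        (cohort$flexibility < 0 | cohort$flexibility > 100),
      "flexibility outside [0, 100]")
  add(!is.na(cohort$number_of_levels_involved) &
        cohort$number_of_levels_involved < 2, "fewer than 2 levels involved")
  bad <- which(lengths(reasons) > 0)
  rejected <- tibble::tibble(
    row = bad,
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "))
  if (length(bad) > 0) {
    message("rejected ", length(bad), " of ", n, " record(s): ",
            paste(unique(rejected$reason), collapse = " | "))
    cohort <- cohort[-bad, , drop = FALSE]
  }
  if (nrow(cohort) == 0) stop("no valid records remain", call. = FALSE)
  attr(cohort, "rejected") <- rejected
  tibble::as_tibble(cohort)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All stage seeds are derived
#' from the single top-level seed by a fixed offset scheme, so each stage
#' is independently reproducible.
#'
#' @param seed Top-level integer seed.
#' @param cohort_file Optional cohort CSV; when NULL a synthetic cohort of
#'   `n` patients is generated.
#' @param n Synthetic cohort size (used when `cohort_file` is NULL).
#' @param folds CV folds. @param test_fraction Held-out fraction.
#' @param family Final model family (currently tuned families of
#'   [default_grids()]).
#' @param grid Hyperparameter grid for the final family.
#' @param selector_trees Forest size used inside feature selection.
#' @param min_size Smallest subset size SBFS descends to.
#' @param ci_multiplier Confidence-bound multiplier for trace tables.
#' @param sim_config A [cohort_sim_config()] for synthetic cohorts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, cohort_file = NULL, n = 193,
                            folds = 5, test_fraction = 0.25, family = "rf",
                            grid = default_grids()[["rf"]],
                            selector_trees = 100, min_size = 1,
                            ci_multiplier = 1.2816,
                            sim_config = cohort_sim_config()) {
  if (!family %in% c("rf", "svm", "ann")) {
    stop("unknown model family: ", family, call. = FALSE)
  }
  structure(list(seed = as.integer(seed), cohort_file = cohort_file, n = n,
                 folds = folds, test_fraction = test_fraction,
                 family = family, grid = grid,
                 selector_trees = selector_trees, min_size = min_size,
                 ci_multiplier = ci_multiplier, sim_config = sim_config),
            class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the end-to-end progression pipeline
#'
#' Executes: cohort (read or generate) -> encode -> 75/25 split -> SBFS on
#' the training split only (no selection leakage) -> grid search over the
#' selected features -> final training -> held-out evaluation; then writes
#' `traces.csv`, `model.json`, `report.json` and `provenance.json` (plus
#' `cohort.csv` for generated cohorts) to `out_dir`. Outputs carry the
#' config hash and seed and are byte-identical across re-runs with the
#' same config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the fitted `bundle`, the `sbfs` result,
#'   the `evaluation`, the encoded splits and the output paths.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 1, n = 60,
#'                       grid = list(n_estimators = 100, max_features = 3)),
#'                     out_dir = tempfile())
#' run$evaluation$mae
#' }
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  generated <- is.null(config$cohort_file)
  cohort <- stage("cohort", {
    if (generated) {
      generate_cohort(n = config$n, seed = stage_seed(config$seed, "cohort"),
                      config = config$sim_config)
    } else {
      read_cohort(config$cohort_file)
    }
  })
  encoded <- stage("features", encode_cohort(cohort))
  feats <- setdiff(names(encoded), "final_major_cobb")
  parts <- stage("split", split_cohort(encoded,
                                       test_fraction = config$test_fraction,
                                       seed = stage_seed(config$seed, "split")))
  X_tr <- parts$train[, feats, drop = FALSE]
  y_tr <- parts$train$final_major_cobb
  X_te <- parts$test[, feats, drop = FALSE]
  y_te <- parts$test$final_major_cobb
  sel <- stage("sbfs", sbfs_select(
    X_tr, y_tr,
    model_factory = rf_factory(n_estimators = config$selector_trees,
                               seed = stage_seed(config$seed, "sbfs")),
    k = config$folds, seed = stage_seed(config$seed, "sbfs"),
    min_size = config$min_size, ci_multiplier = config$ci_multiplier))
  sel_idx <- sel$best$feature_indices[[1]]
  X_tr_sel <- X_tr[, sel_idx + 1L, drop = FALSE]
  X_te_sel <- X_te[, sel_idx + 1L, drop = FALSE]
  gs <- stage("grid_search", grid_search(
    config$family, config$grid, X_tr_sel, y_tr, k = config$folds,
    seed = stage_seed(config$seed, "grid")))
  bundle <- stage("train", train_final(
    config$family, gs$best_params, X_tr_sel, y_tr,
    seed = stage_seed(config$seed, "train"), cv = gs$cv))
  evaluation <- stage("evaluate", evaluate_model(bundle, X_te_sel, y_te))

  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package = "curveprog",
               version = as.character(utils::packageVersion("curveprog")),
               n_patients = nrow(encoded), generated_cohort = generated,
               stages = c("features", "split", "sbfs", "grid_search",
                          "train", "evaluate"))
  paths <- list(
    traces = file.path(out_dir, "traces.csv"),
    model = file.path(out_dir, "model.json"),
    report = file.path(out_dir, "report.json"),
    provenance = file.path(out_dir, "provenance.json"))
  readr::write_csv(
    cbind(trace_report(sel), config_hash = prov$config_hash,
          seed = config$seed),
    paths$traces, progress = FALSE)
  imp <- if (config$family == "rf") feature_importance_rank(bundle) else NULL
  jsonlite::write_json(list(
    config_hash = prov$config_hash, seed = config$seed,
    family = config$family,
    selected_indices = sel_idx,
    selected_features = names(X_tr_sel),
    hyperparameters = gs$best_params,
    cv_train_mae = gs$cv$mean,
    importance = imp), paths$model, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(list(
    config_hash = prov$config_hash, seed = config$seed,
    n_test = evaluation$n, test_mae = evaluation$mae,
    residuals = evaluation$residuals,
    histogram = evaluation$bins), paths$report, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (generated) {
    paths$cohort <- file.path(out_dir, "cohort.csv")
    readr::write_csv(cohort, paths$cohort, progress = FALSE)
  }
  invisible(list(bundle = bundle, sbfs = sel, evaluation = evaluation,
                 grid = gs, cohort = cohort, split = parts, paths = paths,
                 provenance = prov))
}
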