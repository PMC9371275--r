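#' Landmark tables
#'
#' A landmark table is a long-format tibble with one row per vertebral
#' corner point and columns `patient_id`, `visit`, `view`, `level`,
#' `corner`, `x`, `y`. Each vertebra carries exactly four corners labelled
#' `SL` (superior-left), `SR` (superior-right), `IR` (inferior-right) and
#' `IL` (inferior-left). Views are `"standing"`, `"bending-left"` or
#' `"bending-right"`.
#'
#' The internal coordinate convention is x increasing towards the image
#' right and y increasing caudally-to-cranially (so T1 has the largest y).
#' Raw image pixels, where y grows downwards, are converted with
#' [normalize_coordinates()].
#'
#' @name landmark-table
NULL

landmark_cols <- c("patient_id", "visit", "view", "level", "corner", "x", "y")

#' Validate a landmark table
#'
#' Checks the long-format contract: required columns, known corner labels,
#' known levels, exactly the four corners `SL, SR, IR, IL` per
#' (patient, visit, view, level), finite coordinates. All violations are
#' collected and reported together.
#'
#' @param landmarks A landmark table (see [landmark-table]).
#' @return The input, invisibly, with corners ordered SL, SR, IR, IL within
#'   each vertebra.
#' @export
validate_landmarks <- function(landmarks) {
  problems <- character()
  missing <- setdiff(landmark_cols, names(landmarks))
  if (length(missing) > 0) {
    stop("landmark table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_corner <- !landmarks$corner %in% corner_order
  if (any(bad_corner)) {
    problems <- c(problems, paste0(
      "row ", which(bad_corner), ": unknown corner '",
      landmarks$corner[bad_corner], "' (expected SL, SR, IR, IL)"))
  }
  known <- is_standard_level(landmarks$level) |
    grepl("^V[0-9]+$", trimws(landmarks$level))
  if (any(!known)) {
    problems <- c(problems, paste0(
      "row ", which(!known), ": unknown level '", landmarks$level[!known], "'"))
  }
  not_finite <- !is.finite(landmarks$x) | !is.finite(landmarks$y)
  if (any(not_finite)) {
    problems <- c(problems, paste0("row ", which(not_finite),
                                   ": non-finite coordinate"))
  }
  counts <- dplyr::count(
    landmarks,
    dplyr::across(dplyr::all_of(c("patient_id", "visit", "view", "level",
                                  "corner"))))
  dup <- counts[counts$n > 1L, , drop = FALSE]
  if (nrow(dup) > 0) {
    problems <- c(problems, paste0(
      "duplicate corner ", dup$corner, " for level ", dup$level,
      " (patient ", dup$patient_id, ", visit ", dup$visit,
      ", view ", dup$view, ")"))
  }
  per_vert <- dplyr::summarise(
    dplyr::group_by(landmarks,
                    dplyr::across(dplyr::all_of(c("patient_id", "visit",
                                                  "view", "level")))),
    n_corners = dplyr::n_distinct(.data$corner),
    missing_corners = paste(setdiff(corner_order, .data$corner),
                            collapse = ","),
    .groups = "drop")
  incomplete <- per_vert[per_vert$n_corners < 4L, , drop = FALSE]
  if (nrow(incomplete) > 0) {
    problems <- c(problems, paste0(
      "level ", incomplete$level, " (patient ", incomplete$patient_id,
      ", visit ", incomplete$visit, ", view ", incomplete$view,
      ") is missing corner(s) ", incomplete$missing_corners))
  }
  if (length(problems) > 0) {
    stop("invalid landmark table:\n  ",
         paste(sort(problems), collapse = "\n  "), call. = FALSE)
  }
  out <- dplyr::arrange(
    landmarks,
    .data$patient_id, .data$visit, .data$view,
    level_index(.data$level), match(.data$corner, corner_order))
  invisible(tibble::as_tibble(out))
}

#' Normalize landmark coordinates to the internal convention
#'
#' Internally, y increases caudally-to-cranially (T1 on top has the largest
#' y). Image pixel coordinates usually have y increasing downwards; pass
#' `y_down = TRUE` with the image height to flip them (`y <- image_height - y`).
#' The function is idempotent on already-normalized input
#' (`y_down = FALSE`, the default, changes nothing).
#'
#' After conversion the corner labels are checked against the convention:
#' within every vertebra the superior corners must lie cranial to (above)
#' the inferior corners and the left corners to the left of the right
#' corners; a violation indicates mislabelled input and is an error.
#'
#' @param landmarks A landmark table.
#' @param y_down Are the incoming y coordinates image pixels (y increasing
#'   downwards)?
#' @param image_height Image height in pixels; required when `y_down = TRUE`.
#' @return The normalized landmark table.
#' @export
#' @examples
#' lms <- generate_spine_landmarks(spine_sim_config(cobb = 30, seed = 1))$landmarks
#' identical(normalize_coordinates(lms), lms)  # idempotent
normalize_coordinates <- function(landmarks, y_down = FALSE,
                                  image_height = NULL) {
  landmarks <- validate_landmarks(landmarks)
  if (isTRUE(y_down)) {
    if (is.null(image_height)) {
      stop("image_height is required when y_down = TRUE", call. = FALSE)
    }
    landmarks$y <- image_height - landmarks$y
  }
  wide <- tidyr::pivot_wider(landmarks, names_from = "corner",
                             values_from = c("x", "y"))
  sup_y <- (wide$y_SL + wide$y_SR) / 2
  inf_y <- (wide$y_IL + wide$y_IR) / 2
  if (any(sup_y <= inf_y)) {
    bad <- wide[sup_y <= inf_y, , drop = FALSE]
    stop("corner labels inconsistent with the coordinate convention: ",
         "superior corners are not cranial to inferior corners for level(s) ",
         paste(unique(bad$level), collapse = ", "),
         ". Check y_down/image_height or the corner labelling.",
         call. = FALSE)
  }
  left_x <- (wide$x_SL + wide$x_IL) / 2
  right_x <- (wide$x_SR + wide$x_IR) / 2
  if (any(left_x >= right_x)) {
    bad <- wide[left_x >= right_x, , drop = FALSE]
    stop("corner labels inconsistent with the coordinate convention: ",
         "left corners are not left of right corners for level(s) ",
         paste(unique(bad$level), collapse = ", "), call. = FALSE)
  }
  landmarks
}
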