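#' Plot a spine from its landmark table
#'
#' Draws the vertebral outlines, their centroids and the fitted
#' centreline spline for each spine in the table; detected apices are
#' marked.
#'
#' @param landmarks A normalized landmark table.
#' @param min_deviation Apex threshold, as in [find_apices()].
#' @return A ggplot object.
#' @export
plot_spine <- function(landmarks, min_deviation = 2) {
  landmarks <- validate_landmarks(landmarks)
  geoms <- vertebra_geometry(landmarks)
  group_cols <- c("patient_id", "visit", "view")
  spines <- dplyr::group_split(dplyr::group_by(
    geoms, dplyr::across(dplyr::all_of(group_cols))))
  curve_df <- purrr::map_dfr(spines, function(g) {
    curve <- fit_spine_curve(g)
    yy <- seq(min(g$centroid_y), max(g$centroid_y), length.out = 200)
    tibble::tibble(patient_id = g$patient_id[1], visit = g$visit[1],
                   view = g$view[1], x = curve$fun(yy), y = yy)
  })
  apex_df <- purrr::map_dfr(spines, function(g) {
    apices <- find_apices(fit_spine_curve(g), min_deviation = min_deviation)
    if (nrow(apices) == 0) return(NULL)
    tibble::tibble(patient_id = g$patient_id[1], visit = g$visit[1],
                   view = g$view[1], x = apices$extremum_x,
                   y = apices$extremum_y, level = apices$level)
  })
  poly <- dplyr::mutate(
    landmarks,
    vertebra = paste(.data$patient_id, .data$visit, .data$view, .data$level))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = poly,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$vertebra),
      fill = "grey85", colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_path(data = curve_df,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_point(data = geoms,
                        ggplot2::aes(x = .data$centroid_x,
                                     y = .data$centroid_y), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~ patient_id + visit + view) +
    ggplot2::labs(x = "lateral position (px)",
                  y = "cranio-caudal position (px)")
  if (nrow(apex_df) > 0) {
    p <- p + ggplot2::geom_point(
      data = apex_df, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick", shape = 4, size = 3, stroke = 1.2)
  }
  p
}

#' @export
autoplot.cobb_sbfs <- function(object, ...) {
  df <- tidy(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mean_mae)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_mae - .data$ci_bound,
                   ymax = .data$mean_mae + .data$ci_bound,
                   colour = .data$best)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "subset rank (ascending CV MAE)",
                  y = "cross-validated MAE (degrees)",
                  title = "Floating backward selection traces")
}

#' @export
autoplot.cobb_model <- function(object, ...) {
  if (object$family != "rf") {
    stop("autoplot is defined for random-forest bundles (importances)",
         call. = FALSE)
  }
  imp <- feature_importance_rank(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$weight,
    y = stats::reorder(.data$feature, .data$weight))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "importance weight", y = NULL,
                  title = "Feature importance (impurity)")
}

#' @export
autoplot.cobb_evaluation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$residual)) +
    ggplot2::geom_histogram(binwidth = object$bins$bin_hi[1] -
                              object$bins$bin_lo[1],
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "prediction error (degrees)", y = "patients",
                  title = sprintf("Held-out prediction error (MAE %.2f deg)",
                                  object$mae))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
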