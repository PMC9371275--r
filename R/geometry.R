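#' Polygon area moments
#'
#' Shoelace-based area, centroid and second central area moments of a simple
#' polygon. Vertex order may be clockwise or counter-clockwise. The second
#' central moments are returned per unit area (i.e. the covariance matrix of
#' the uniform distribution over the polygon's interior).
#'
#' @param x,y Vertex coordinates (not repeated at the end).
#' @return List with `area` (> 0), `centroid` (length-2), and `mu` the
#'   2x2 second central moment matrix.
#' @keywords internal
polygon_moments <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (a < 0) {  # reverse to counter-clockwise
    x <- rev(x); y <- rev(y)
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    a <- sum(cross) / 2
  }
  if (abs(a) < .Machine$double.eps * 100 * max(1, max(abs(x)), max(abs(y)))^2) {
    stop("degenerate vertebra polygon: zero area", call. = FALSE)
  }
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  # Second moments about the origin, then shifted to the centroid.
  ixx <- sum((y^2 + y * yn + yn^2) * cross) / 12      # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cross) / 12      # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  mu_xx <- iyy / a - cx^2
  mu_yy <- ixx / a - cy^2
  mu_xy <- ixy / a - cx * cy
  list(area = a, centroid = c(cx, cy),
       mu = matrix(c(mu_xx, mu_xy, mu_xy, mu_yy), 2, 2))
}

# Major-axis angle (degrees, counter-clockwise from horizontal, in
# (-90, 90]) of a second-moment matrix; NA when isotropic.
principal_angle <- function(mu, tol = 1e-10) {
  d <- mu[1, 1] - mu[2, 2]
  o <- 2 * mu[1, 2]
  if (d^2 + o^2 <= (tol * (mu[1, 1] + mu[2, 2]))^2) {
    return(NA_real_)
  }
  ang <- 0.5 * atan2(o, d) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

# Angle between two line directions, folded to [0, 90].
line_angle_between <- function(v1, v2) {
  a1 <- atan2(v1[2], v1[1])
  a2 <- atan2(v2[2], v2[1])
  d <- abs(a1 - a2) * 180 / pi
  d <- d %% 180
  if (d > 90) d <- 180 - d
  d
}

#' Per-vertebra geometry from corner landmarks
#'
#' For every vertebra in a normalized landmark table, fits the polygon
#' through its four corners and reduces it to the equivalent ellipse: the
#' centroid is the polygon's area centroid, and the orientation is the
#' angle of the major principal axis of the polygon's second central area
#' moments, in degrees from the horizontal (counter-clockwise positive,
#' range (-90, 90]). For a rectangle this equals the rectangle's rotation
#' exactly. The wedge angle is the angle between the superior (SL-SR) and
#' inferior (IL-IR) endplate lines, in [0, 90].
#'
#' When the moment tensor is isotropic (a square vertebra: principal axes
#' undefined), the orientation falls back to the superior endplate
#' direction and the row is flagged `isotropic = TRUE`.
#'
#' @param landmarks A normalized landmark table.
#' @return A tibble with one row per vertebra: `patient_id`, `visit`,
#'   `view`, `level`, `centroid_x`, `centroid_y`, `orientation_deg`,
#'   `wedge_deg`, `isotropic`, ordered cranio-caudally within each spine.
#' @export
#' @examples
#' lms <- generate_spine_landmarks(spine_sim_config(cobb = 40, seed = 1))$landmarks
#' vertebra_geometry(lms)
vertebra_geometry <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  one <- function(df) {
    df <- df[match(corner_order, df$corner), , drop = FALSE]
    m <- polygon_moments(df$x, df$y)
    pt <- function(corner) unname(c(df$x[df$corner == corner],
                                    df$y[df$corner == corner]))
    sup <- pt("SR") - pt("SL")
    inf <- pt("IR") - pt("IL")
    ang <- principal_angle(m$mu)
    iso <- is.na(ang)
    if (iso) {
      ang <- atan2(sup[2], sup[1]) * 180 / pi
      if (ang <= -90) ang <- ang + 180
      if (ang > 90) ang <- ang - 180
    }
    tibble::tibble(centroid_x = m$centroid[1], centroid_y = m$centroid[2],
                   orientation_deg = ang,
                   wedge_deg = line_angle_between(sup, inf),
                   isotropic = iso)
  }
  out <- dplyr::reframe(
    dplyr::group_by(landmarks,
                    dplyr::across(dplyr::all_of(c("patient_id", "visit",
                                                  "view", "level")))),
    one(dplyr::pick(dplyr::everything())))
  out <- dplyr::ungroup(out)
  dplyr::arrange(out, .data$patient_id, .data$visit, .data$view,
                 dplyr::desc(.data$centroid_y))
}

#' Fit the spine centreline spline
#'
#' Fits a natural cubic interpolating spline of lateral centroid position
#' x against cranio-caudal position y through the vertebral centroids of a
#' single spine, and locates its interior local extrema (the candidate
#' curve apices).
#'
#' @param geoms A [vertebra_geometry()] tibble for one
#'   (patient, visit, view) spine, with at least 4 vertebrae.
#' @return An object of class `spine_curve`: a list with the interpolant
#'   `fun`, the extrema tibble (`y`, `x`, `deviation`, `side`), the chord
#'   through the endmost centroids, and the source centroids. `deviation`
#'   is the signed lateral offset of each extremum from the chord
#'   (positive towards +x).
#' @export
fit_spine_curve <- function(geoms) {
  if (nrow(geoms) < 4) {
    stop("spine curve fitting needs at least 4 vertebrae, got ", nrow(geoms),
         call. = FALSE)
  }
  if (length(unique(geoms$level)) != nrow(geoms)) {
    stop("duplicate levels in geometry table", call. = FALSE)
  }
  ord <- order(geoms$centroid_y, decreasing = TRUE)  # cranial first
  yy <- geoms$centroid_y[ord]
  xx <- geoms$centroid_x[ord]
  if (any(diff(yy) >= 0)) {
    stop("centroid cranio-caudal coordinates are not strictly monotone; ",
         "re-order or reject the landmark set", call. = FALSE)
  }
  fun <- stats::splinefun(yy, xx, method = "natural")
  # Interior extrema: sign changes of the derivative on a dense grid,
  # refined by root-finding on the derivative.
  grid <- seq(min(yy), max(yy), length.out = max(512L, 32L * nrow(geoms)))
  d1 <- fun(grid, deriv = 1)
  flips <- which(d1[-1] * d1[-length(d1)] < 0)
  ext_y <- purrr::map_dbl(flips, function(i) {
    stats::uniroot(function(y) fun(y, deriv = 1),
                   lower = grid[i], upper = grid[i + 1],
                   tol = 1e-10)$root
  })
  ext_y <- sort(unique(ext_y), decreasing = TRUE)
  # chord through the endmost centroids
  chord <- function(y) {
    xx[1] + (xx[length(xx)] - xx[1]) * (y - yy[1]) / (yy[length(yy)] - yy[1])
  }
  extrema <- tibble::tibble(
    y = ext_y,
    x = fun(ext_y),
    deviation = fun(ext_y) - chord(ext_y))
  extrema$side <- ifelse(extrema$deviation >= 0, "right", "left")
  structure(list(fun = fun, extrema = extrema, chord = chord,
                 centroids = tibble::tibble(level = geoms$level[ord],
                                            x = xx, y = yy)),
            class = "spine_curve")
}

#' @export
print.spine_curve <- function(x, ...) {
  cat("<spine_curve> ", nrow(x$centroids), " centroids, ",
      nrow(x$extrema), " interior extrema\n", sep = "")
  invisible(x)
}

#' Locate curve apices on a fitted spine curve
#'
#' Each interior extremum of the centreline whose lateral deviation from
#' the chord joining the endmost centroids exceeds `min_deviation`
#' nominates one apex: the vertebra whose centroid is nearest (Euclidean)
#' to the extremum point; distance ties go to the more cranial vertebra.
#' A straight spine yields zero apices (not an error).
#'
#' @param curve A [fit_spine_curve()] object.
#' @param min_deviation Minimum |lateral deviation| (same units as the
#'   landmarks, default 2 px) for an extremum to count as an apex.
#' @return Tibble of apices, cranial first: `level`, `extremum_x`,
#'   `extremum_y`, `deviation`, `side`.
#' @export
find_apices <- function(curve, min_deviation = 2) {
  stopifnot(inherits(curve, "spine_curve"))
  ext <- curve$extrema[abs(curve$extrema$deviation) > min_deviation, ,
                       drop = FALSE]
  if (nrow(ext) == 0) {
    return(tibble::tibble(level = character(), extremum_x = double(),
                          extremum_y = double(), deviation = double(),
                          side = character()))
  }
  cen <- curve$centroids
  lvl <- purrr::map_chr(seq_len(nrow(ext)), function(i) {
    d <- sqrt((cen$x - ext$x[i])^2 + (cen$y - ext$y[i])^2)
    # ties -> more cranial; centroids are stored cranial-first
    cen$level[which.min(d)]
  })
  tibble::tibble(level = lvl, extremum_x = ext$x, extremum_y = ext$y,
                 deviation = ext$deviation, side = ext$side)
}

#' Measure one scoliotic curve about an apex
#'
#' Finds the end vertebrae and the Cobb angle of the curve whose apex is
#' `apex_level`. The upper end vertebra is the most tilted vertebra
#' (maximum |orientation|) cranial to the apex, the lower end the most
#' tilted caudal to it; exact ties go to the vertebra farther from the
#' apex. When no candidate on a side is tilted at all (every orientation
#' exactly zero - a degenerate straight segment) the end defaults to the
#' vertebra adjacent to the apex. The Cobb angle is the absolute
#' difference of the signed end-vertebra orientations.
#'
#' For multi-curve spines the search for each curve's ends must not cross
#' into the neighbouring curve: `upper_limit` / `lower_limit` (exclusive)
#' bound the candidate range, and [measure_all()] sets them to the
#' adjacent apices.
#'
#' @param geoms A [vertebra_geometry()] tibble for one spine.
#' @param apex_level Level label of the apex; must have at least one
#'   vertebra cranial and one caudal to it.
#' @param side Optional convexity side carried from [find_apices()].
#' @param upper_limit,lower_limit Optional level labels bounding the end
#'   search (exclusive); typically the adjacent apices.
#' @return One-row tibble: `apex`, `upper_end`, `lower_end`, `cobb_deg`,
#'   `levels` (inclusive count of involved levels), `side`.
#' @export
measure_curve <- function(geoms, apex_level, side = NA_character_,
                          upper_limit = NULL, lower_limit = NULL) {
  geoms <- dplyr::arrange(geoms, dplyr::desc(.data$centroid_y))
  ai <- which(geoms$level == apex_level)
  if (length(ai) != 1) {
    stop("apex level ", apex_level, " not found exactly once", call. = FALSE)
  }
  if (ai == 1 || ai == nrow(geoms)) {
    stop("apex at the boundary of the instrumented set: no vertebra ",
         if (ai == 1) "cranial" else "caudal", " to ", apex_level,
         call. = FALSE)
  }
  pick_end <- function(idx, apex_idx) {
    tilt <- abs(geoms$orientation_deg[idx])
    if (max(tilt) == 0) {  # untilted segment: default to the adjacent vertebra
      return(idx[which.min(abs(idx - apex_idx))])
    }
    best <- idx[tilt == max(tilt)]
    best[which.max(abs(best - apex_idx))]
  }
  upper_candidates <- seq_len(ai - 1L)
  if (!is.null(upper_limit)) {
    bi <- which(geoms$level == upper_limit)
    if (length(bi) == 1) upper_candidates <- upper_candidates[upper_candidates > bi]
  }
  lower_candidates <- seq(ai + 1L, nrow(geoms))
  if (!is.null(lower_limit)) {
    bi <- which(geoms$level == lower_limit)
    if (length(bi) == 1) lower_candidates <- lower_candidates[lower_candidates < bi]
  }
  # an adjacent apex leaves no vertebra strictly between the two curves;
  # the shared end then defaults to the vertebra next to this apex
  if (length(upper_candidates) == 0) upper_candidates <- ai - 1L
  if (length(lower_candidates) == 0) lower_candidates <- ai + 1L
  ui <- pick_end(upper_candidates, ai)
  li <- pick_end(lower_candidates, ai)
  tibble::tibble(
    apex = apex_level,
    upper_end = geoms$level[ui],
    lower_end = geoms$level[li],
    cobb_deg = abs(geoms$orientation_deg[ui] - geoms$orientation_deg[li]),
    levels = li - ui + 1L,
    side = side)
}

#' Measure all curves of every spine in a landmark table
#'
#' Runs the full measurement chain per (patient, visit, view) spine:
#' vertebral geometry, centreline spline, apex detection, and per-apex
#' curve measurement. The curve with the greatest Cobb angle in each spine
#' is flagged major (Cobb ties go to the more cranial apex). A straight
#' spine contributes no rows.
#'
#' @param landmarks A normalized landmark table.
#' @param min_deviation Apex qualification threshold, see [find_apices()].
#' @return Tibble with one row per detected curve: `patient_id`, `visit`,
#'   `view`, `apex`, `upper_end`, `lower_end`, `cobb_deg`, `levels`,
#'   `side`, `major`.
#' @export
#' @examples
#' sim <- generate_spine_landmarks(spine_sim_config(cobb = 40, seed = 1))
#' measure_all(sim$landmarks)
measure_all <- function(landmarks, min_deviation = 2) {
  geoms <- vertebra_geometry(landmarks)
  one_spine <- function(g) {
    if (nrow(g) < 4) {
      stop("curve measurement needs at least 4 vertebrae, got ", nrow(g),
           call. = FALSE)
    }
    curve <- fit_spine_curve(g)
    apices <- find_apices(curve, min_deviation = min_deviation)
    if (nrow(apices) == 0) {
      return(tibble::tibble(apex = character(), upper_end = character(),
                            lower_end = character(), cobb_deg = double(),
                            levels = integer(), side = character(),
                            major = logical()))
    }
    # drop apices that landed on a boundary vertebra (no curve to measure)
    boundary <- apices$level %in% c(curve$centroids$level[1],
                                    curve$centroids$level[nrow(curve$centroids)])
    if (any(boundary)) {
      warning("skipping apex at boundary vertebra: ",
              paste(apices$level[boundary], collapse = ", "), call. = FALSE)
      apices <- apices[!boundary, , drop = FALSE]
    }
    if (nrow(apices) == 0) {
      return(tibble::tibble(apex = character(), upper_end = character(),
                            lower_end = character(), cobb_deg = double(),
                            levels = integer(), side = character(),
                            major = logical()))
    }
    # bound each curve's end search at the neighbouring apices so a curve
    # never claims end vertebrae inside an adjacent curve
    curves <- purrr::map_dfr(seq_len(nrow(apices)), function(i) {
      measure_curve(
        g, apices$level[i], side = apices$side[i],
        upper_limit = if (i > 1) apices$level[i - 1] else NULL,
        lower_limit = if (i < nrow(apices)) apices$level[i + 1] else NULL)
    })
    # major = greatest Cobb; ties -> more cranial apex (rows are cranial-first)
    curves$major <- seq_len(nrow(curves)) == which.max(curves$cobb_deg)
    curves
  }
  out <- dplyr::reframe(
    dplyr::group_by(geoms,
                    dplyr::across(dplyr::all_of(c("patient_id", "visit",
                                                  "view")))),
    one_spine(dplyr::pick(dplyr::everything())))
  tibble::as_tibble(dplyr::ungroup(out))
}
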