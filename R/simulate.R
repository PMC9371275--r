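#' Spine simulation configuration
#'
#' Defines a synthetic scoliotic spine with known geometric ground truth.
#' The centreline of a single-bump spine is `x(y) = A * sin(pi * y / L)`
#' with amplitude `A = (L / pi) * tan(cobb * pi / 360)`, so the maximal
#' tangent angles at the two ends are exactly `+/- cobb / 2` degrees and
#' the analytic Cobb angle equals `cobb`. An s-curve concatenates two
#' opposed bumps with independently specified Cobb angles. Vertebrae are
#' rectangles of the given width and height placed at equal arc-length
#' intervals, rotated to the local tangent, with optional isotropic
#' Gaussian landmark noise.
#'
#' @param n_vertebrae Number of vertebrae (default 17, labelled T1..L5;
#'   other counts up to 17 use the leading labels, larger counts use
#'   generic labels V1..Vn).
#' @param length Spine length L in pixels (cranio-caudal extent).
#' @param cobb True Cobb angle in degrees, in \[0, 120); for an s-curve,
#'   the upper (thoracic) bump.
#' @param cobb2 Lower-bump Cobb angle for `shape = "s-curve"`.
#' @param shape `"single-bump"` or `"s-curve"`.
#' @param split_fraction Fraction of the length occupied by the upper
#'   bump of an s-curve (default 0.5).
#' @param width,height Vertebral body width and height in pixels.
#' @param noise_sd Isotropic Gaussian landmark noise SD in pixels.
#' @param convexity `"right"` or `"left"` convexity of the (upper) bump.
#' @param seed Integer seed.
#' @return A `spine_sim_config` list.
#' @export
spine_sim_config <- function(n_vertebrae = 17, length = 850, cobb = 40,
                             cobb2 = NULL, shape = c("single-bump", "s-curve"),
                             split_fraction = 0.5, width = 45, height = 24,
                             noise_sd = 0, convexity = c("right", "left"),
                             seed = 1) {
  shape <- match.arg(shape)
  convexity <- match.arg(convexity)
  if (n_vertebrae < 5) stop("need at least 5 vertebrae", call. = FALSE)
  if (cobb < 0 || cobb >= 120) stop("cobb must lie in [0, 120)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (shape == "s-curve" && is.null(cobb2)) {
    stop("s-curve needs cobb2", call. = FALSE)
  }
  structure(list(n_vertebrae = as.integer(n_vertebrae), length = length,
                 cobb = cobb, cobb2 = cobb2, shape = shape,
                 split_fraction = split_fraction, width = width,
                 height = height, noise_sd = noise_sd,
                 convexity = convexity, seed = as.integer(seed)),
            class = "spine_sim_config")
}

# centreline x(y) and its derivative for a config; y in [0, L], cranial at L
centreline_fun <- function(cfg) {
  sgn <- if (cfg$convexity == "right") 1 else -1
  deg2rad <- pi / 180
  if (cfg$shape == "single-bump") {
    L <- cfg$length
    A <- sgn * (L / pi) * tan(cfg$cobb / 2 * deg2rad)
    list(x = function(y) A * sin(pi * y / L),
         dx = function(y) A * (pi / L) * cos(pi * y / L))
  } else {
    L <- cfg$length
    L1 <- L * (1 - cfg$split_fraction)  # junction height: lower bump below
    A_up <- sgn * ((L - L1) / pi) * tan(cfg$cobb / 2 * deg2rad)
    A_lo <- -sgn * (L1 / pi) * tan(cfg$cobb2 / 2 * deg2rad)
    list(
      x = function(y) {
        ifelse(y >= L1,
               A_up * sin(pi * (y - L1) / (L - L1)),
               A_lo * sin(pi * (L1 - y) / L1))
      },
      dx = function(y) {
        ifelse(y >= L1,
               A_up * (pi / (L - L1)) * cos(pi * (y - L1) / (L - L1)),
               -A_lo * (pi / L1) * cos(pi * (L1 - y) / L1))
      })
  }
}

#' Generate a synthetic scoliotic spine as a landmark table
#'
#' Places `n_vertebrae` rectangular vertebrae at equal arc-length
#' intervals along the configured centreline, each rotated to the local
#' tangent, and emits their four corner landmarks (with seeded isotropic
#' Gaussian noise when `noise_sd > 0`). Ground truth (the analytic Cobb
#' angle, apex and end vertebrae) is returned alongside.
#'
#' @param cfg A [spine_sim_config()].
#' @param patient_id,visit,view Identifiers stamped on the landmark rows.
#' @return List with `landmarks` (a [landmark-table]) and `truth`
#'   (list: `cobb`, `apex_level`, `apex_index`, `upper_end`, `lower_end`,
#'   `convexity`; for an s-curve, a list of two such records plus the
#'   per-level assignment). The config is attached as attribute `config`.
#' @export
#' @examples
#' sim <- generate_spine_landmarks(spine_sim_config(cobb = 40, seed = 7))
#' sim$truth$cobb
generate_spine_landmarks <- function(cfg, patient_id = "sim", visit = 1L,
                                     view = "standing") {
  stopifnot(inherits(cfg, "spine_sim_config"))
  n <- cfg$n_vertebrae
  L <- cfg$length
  cl <- centreline_fun(cfg)
  # arc length from the caudal end, on a fine grid
  grid_y <- seq(0, L, length.out = 4096)
  speed <- sqrt(1 + cl$dx(grid_y)^2)
  arc <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(grid_y)))
  total_arc <- arc[length(arc)]
  spacing <- total_arc / (n - 1)
  if (cfg$height >= spacing) {
    stop("vertebra height (", cfg$height, ") reaches the inter-vertebral ",
         "arc spacing (", round(spacing, 1), "): vertebrae would overlap; ",
         "reduce height or the Cobb angle", call. = FALSE)
  }
  targets <- seq(0, total_arc, length.out = n)
  centre_y <- stats::approx(arc, grid_y, xout = targets)$y
  centre_y[1] <- 0; centre_y[n] <- L
  centre_y <- rev(centre_y)               # cranial (y = L) first
  centre_x <- cl$x(centre_y)
  tilt <- atan(cl$dx(centre_y))           # endplate tilt from horizontal
  levels <- if (n <= 17) spinal_levels()[seq_len(n)] else paste0("V", seq_len(n))
  hw <- cfg$width / 2
  hh <- cfg$height / 2
  set.seed(cfg$seed)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    e <- c(cos(tilt[i]), sin(tilt[i]))    # endplate direction
    nrm <- c(-sin(tilt[i]), cos(tilt[i])) # superior normal
    corners <- rbind(
      SL = c(centre_x[i], centre_y[i]) - hw * e + hh * nrm,
      SR = c(centre_x[i], centre_y[i]) + hw * e + hh * nrm,
      IR = c(centre_x[i], centre_y[i]) + hw * e - hh * nrm,
      IL = c(centre_x[i], centre_y[i]) - hw * e - hh * nrm)
    tibble::tibble(patient_id = patient_id, visit = as.integer(visit),
                   view = view, level = levels[i],
                   corner = rownames(corners),
                   x = corners[, 1], y = corners[, 2])
  })
  if (cfg$noise_sd > 0) {
    rows$x <- rows$x + stats::rnorm(nrow(rows), sd = cfg$noise_sd)
    rows$y <- rows$y + stats::rnorm(nrow(rows), sd = cfg$noise_sd)
  }
  truth <- if (cfg$shape == "single-bump") {
    apex_index <- which.min(abs(centre_y - L / 2))
    list(cobb = cfg$cobb, apex_level = levels[apex_index],
         apex_index = apex_index, upper_end = levels[1],
         lower_end = levels[n], convexity = cfg$convexity)
  } else {
    L1 <- L * (1 - cfg$split_fraction)
    junction <- which.min(abs(centre_y - L1))
    apex_up <- which.min(abs(centre_y - (L + L1) / 2))
    apex_lo <- which.min(abs(centre_y - L1 / 2))
    list(curves = list(
      upper = list(cobb = cfg$cobb, apex_level = levels[apex_up],
                   apex_index = apex_up, upper_end = levels[1],
                   lower_end = levels[junction], convexity = cfg$convexity),
      lower = list(cobb = cfg$cobb2, apex_level = levels[apex_lo],
                   apex_index = apex_lo, upper_end = levels[junction],
                   lower_end = levels[n],
                   convexity = setdiff(c("right", "left"), cfg$convexity))))
  }
  structure(list(landmarks = rows, truth = truth), config = cfg)
}

#' Generate the side-bending counterpart of a standing spine
#'
#' Regenerates the same spine with its true Cobb angle(s) reduced to
#' `cobb * (1 - flexibility / 100)`, emulating a corrective side-bending
#' radiograph of a curve with the given flexibility. The bend is towards
#' the curve's convexity (the corrective direction); the view label
#' records which side.
#'
#' @param standing The list returned by [generate_spine_landmarks()].
#' @param flexibility Percent, in \[0, 100\].
#' @param seed Optional seed for the bending acquisition's landmark noise
#'   (defaults to the standing seed + 1).
#' @return Same structure as [generate_spine_landmarks()].
#' @export
generate_bending_set <- function(standing, flexibility, seed = NULL) {
  cfg <- attr(standing, "config")
  if (is.null(cfg)) stop("standing must come from generate_spine_landmarks()",
                         call. = FALSE)
  if (flexibility < 0 || flexibility > 100) {
    stop("flexibility must lie in [0, 100]", call. = FALSE)
  }
  shrink <- 1 - flexibility / 100
  cfg_b <- cfg
  cfg_b$cobb <- cfg$cobb * shrink
  if (!is.null(cfg$cobb2)) cfg_b$cobb2 <- cfg$cobb2 * shrink
  cfg_b$seed <- if (is.null(seed)) cfg$seed + 1L else as.integer(seed)
  generate_spine_landmarks(cfg_b, view = paste0("bending-", cfg$convexity))
}

# inverse-CDF truncated normal (exact, seedable)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi <= p_lo) {
    stop("infeasible truncation bounds [", lo, ", ", hi, "] for mean ",
         mean, ", sd ", sd, call. = FALSE)
  }
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Cohort simulation configuration
#'
#' Marginal targets and outcome model for the synthetic AIS cohort. The
#' continuous marginals are truncated normals with the means, SDs and
#' ranges of the study population (initial major Cobb 48.9 +/- 13.9
#' degrees on 10.9-99.5, etc.); categorical features are sampled from the
#' observed category frequencies (169/193 female, Lenke type mix, apex
#' support T6-L3, ...). The outcome is
#' `final = initial + delta0 + sum(beta_j * z_j) + eps`,
#' `eps ~ N(0, sigma)`, where `z_j` are standardized features and the
#' default coefficient ordering gives the initial Cobb angle the dominant
#' effect, flexibility the second largest (progression decreasing in
#' flexibility and skeletal maturity), then lordosis, kyphosis, age at
#' last visit, levels involved and Risser stage. The final angle is
#' floored at 25 degrees, mimicking a surgical cohort.
#'
#' @param sigma Outcome noise SD in degrees (default 4).
#' @param delta0 Mean progression in degrees (default 10.5).
#' @param beta Named numeric vector of effects, degrees per SD of the
#'   named feature.
#' @param floor_final Lower clip for the final Cobb angle (degrees).
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(sigma = 4, delta0 = 10.5,
                              beta = c(initial_major_cobb_angle = 5,
                                       flexibility = -3.5,
                                       initial_lumbar_lordosis_angle = 2,
                                       initial_thoracic_kyphosis_angle = 1.7,
                                       age_at_last_visit = 1.4,
                                       number_of_levels_involved = 1,
                                       risser_plus_stage = -0.7),
                              floor_final = 25) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  marginals <- list(
    initial_major_cobb_angle = list(mean = 48.9, sd = 13.9, lo = 10.9, hi = 99.5),
    initial_thoracic_kyphosis_angle = list(mean = 24.2, sd = 10.9, lo = 0, hi = 51.3),
    initial_lumbar_lordosis_angle = list(mean = 53.6, sd = 12.1, lo = 3.4, hi = 87.1),
    age_at_first_visit = list(mean = 12.7, sd = 1.7, lo = 10, hi = 17.8),
    time_span = list(mean = 0.9, sd = 1, lo = 0.08, hi = 6.5),
    # printed mean inconsistent with its 0-21 range; read as 5.7 degrees
    apex_wedge_angle = list(mean = 5.7, sd = 4.1, lo = 0, hi = 21),
    flexibility = list(mean = 57, sd = 19.3, lo = 5, hi = 99),
    apex_axial_rotation = list(mean = 20.9, sd = 7.9, lo = 0.02, hi = 41.6))
  # age at last visit is derived (first + span); these stats standardize it
  age_last_stats <- list(mean = 13.6, sd = 1.6)
  categorical <- list(
    gender = c("F" = 169, "M" = 24),
    lenke_type = stats::setNames(c(116, 11, 38, 1, 15, 12), 1:6),
    brace_status = c("brace" = 143, "no-brace" = 50),
    apex_location = stats::setNames(c(3, 14, 59, 61, 17, 7, 8, 14, 9, 1),
                                    c(paste0("T", 6:12), paste0("L", 1:3))),
    number_of_levels_involved = stats::setNames(c(2, 7, 44, 76, 44, 12, 8),
                                                4:10),
    risser_plus_stage = stats::setNames(c(74, 38, 10, 14, 13, 12, 16, 16),
                                        risser_vocabulary))
  structure(list(marginals = marginals, age_last_stats = age_last_stats,
                 categorical = categorical, beta = beta, delta0 = delta0,
                 sigma = sigma, floor_final = floor_final),
            class = "cohort_sim_config")
}

# mean/sd of a discrete distribution given category codes and counts
discrete_stats <- function(codes, counts) {
  p <- counts / sum(counts)
  m <- sum(codes * p)
  list(mean = m, sd = sqrt(sum((codes - m)^2 * p)))
}

#' Generate a synthetic AIS cohort
#'
#' Draws `n` patient records from the configured marginals (continuous
#' features from truncated normals, categoricals from the configured
#' frequencies), enforces internal consistency (age at last visit = age at
#' first visit + time span), and generates the final major Cobb angle from
#' the configured linear progression model plus Gaussian noise. The
#' generating coefficients are attached as ground truth.
#'
#' @param n Number of patients (default 193, the study size). Must be
#'   at least 20.
#' @param seed Integer seed.
#' @param config A [cohort_sim_config()].
#' @return A raw cohort tibble (one row per patient, human-readable
#'   encodings, plus `final_major_cobb`) with attribute `truth`: list
#'   with `beta`, `delta0`, `sigma`, `floor_final` and `total_effects`
#'   (the absolute standardized effect of each feature on the final
#'   angle, the generator's importance ground truth). Retrieve it with
#'   [cohort_truth()].
#' @export
#' @examples
#' coh <- generate_cohort(n = 50, seed = 1)
#' cohort_truth(coh)$total_effects
generate_cohort <- function(n = 193, seed = 1, config = cohort_sim_config()) {
  if (n < 20) stop("n must be at least 20", call. = FALSE)
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(seed)
  m <- config$marginals
  draw <- function(nm) {
    s <- m[[nm]]
    rtruncnorm(n, s$mean, s$sd, s$lo, s$hi)
  }
  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    initial_lumbar_lordosis_angle = draw("initial_lumbar_lordosis_angle"),
    initial_thoracic_kyphosis_angle = draw("initial_thoracic_kyphosis_angle"),
    age_at_first_visit = draw("age_at_first_visit"),
    time_span = draw("time_span"),
    apex_wedge_angle = draw("apex_wedge_angle"),
    flexibility = draw("flexibility"),
    apex_axial_rotation = draw("apex_axial_rotation"),
    initial_major_cobb_angle = draw("initial_major_cobb_angle"))
  cohort$age_at_last_visit <- cohort$age_at_first_visit + cohort$time_span
  for (nm in names(config$categorical)) {
    counts <- config$categorical[[nm]]
    cohort[[nm]] <- sample(names(counts), n, replace = TRUE,
                           prob = counts / sum(counts))
  }
  cohort$lenke_type <- as.integer(cohort$lenke_type)
  cohort$number_of_levels_involved <- as.integer(cohort$number_of_levels_involved)

  # standardized features entering the progression model
  z_of <- function(nm) {
    if (nm == "age_at_last_visit") {
      s <- config$age_last_stats
      (cohort$age_at_last_visit - s$mean) / s$sd
    } else if (nm %in% names(m)) {
      s <- m[[nm]]
      (cohort[[nm]] - s$mean) / s$sd
    } else if (nm == "number_of_levels_involved") {
      counts <- config$categorical[[nm]]
      st <- discrete_stats(as.numeric(names(counts)), counts)
      (cohort[[nm]] - st$mean) / st$sd
    } else if (nm == "risser_plus_stage") {
      counts <- config$categorical[[nm]]
      st <- discrete_stats(encode_risser_plus(names(counts)), counts)
      (encode_risser_plus(cohort[[nm]]) - st$mean) / st$sd
    } else {
      stop("no standardization defined for effect feature ", nm,
           call. = FALSE)
    }
  }
  delta <- config$delta0
  for (nm in names(config$beta)) {
    delta <- delta + config$beta[[nm]] * z_of(nm)
  }
  eps <- stats::rnorm(n, 0, config$sigma)
  cohort$final_major_cobb <- pmax(
    cohort$initial_major_cobb_angle + delta + eps, config$floor_final)

  # total absolute standardized effect on the final angle: the identity
  # term gives the initial Cobb angle its own SD on top of its beta
  total <- abs(config$beta)
  total["initial_major_cobb_angle"] <-
    m$initial_major_cobb_angle$sd + config$beta[["initial_major_cobb_angle"]]
  cols <- c("patient_id", feature_table()$column, "final_major_cobb")
  cohort <- cohort[, cols]
  attr(cohort, "truth") <- list(beta = config$beta, delta0 = config$delta0,
                                sigma = config$sigma,
                                floor_final = config$floor_final,
                                total_effects = sort(total, decreasing = TRUE))
  cohort
}

#' Ground truth of a generated cohort
#'
#' @param cohort A tibble from [generate_cohort()] (or one carrying its
#'   `truth` attribute).
#' @return The truth list (generating coefficients, noise SD, total
#'   standardized effects).
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth", exact = TRUE)
  if (is.null(truth)) stop("cohort carries no generator ground truth",
                           call. = FALSE)
  truth
}

#' Append null (uninformative) features to an encoded cohort
#'
#' Adds `m` independent standard-normal columns, uncorrelated with the
#' outcome by construction - the specificity fixture for feature
#' selection: a sound selector should exclude them from its best subset.
#'
#' @param encoded An [encode_cohort()] tibble (features, optionally with
#'   `final_major_cobb` last).
#' @param m Number of null columns (>= 1). @param seed Integer seed.
#' @return The augmented tibble, nulls inserted before the target column,
#'   with attribute `null_indices` (their 0-based feature indices).
#' @export
inject_null_features <- function(encoded, m = 3, seed = 1) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  set.seed(seed)
  has_target <- "final_major_cobb" %in% names(encoded)
  feats <- encoded[, setdiff(names(encoded), "final_major_cobb"), drop = FALSE]
  p0 <- ncol(feats)
  for (j in seq_len(m)) {
    feats[[paste0("null_", j)]] <- stats::rnorm(nrow(feats))
  }
  if (has_target) feats$final_major_cobb <- encoded$final_major_cobb
  attr(feats, "null_indices") <- seq(p0, p0 + m - 1L)
  feats
}
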