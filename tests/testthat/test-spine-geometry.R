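test_that("rectangle geometry matches the analytic values", {
  g <- vertebra_geometry(rect_vertebra(cx = 20, cy = 10, w = 40, h = 20))
  expect_equal(g$centroid_x, 20)
  expect_equal(g$centroid_y, 10)
  expect_equal(g$orientation_deg, 0)
  expect_equal(g$wedge_deg, 0)
  expect_false(g$isotropic)
})

test_that("equivalent-ellipse orientation co-rotates with a rigid rotation", {
  # analytic oracle: rotating the second-moment tensor rotates its
  # principal axis by the same angle, so for rectangles the orientation
  # must equal the applied rotation exactly
  for (ang in c(-45, -7, 3, 7, 30, 60, 89)) {
    g <- vertebra_geometry(rect_vertebra(angle_deg = ang))
    expect_equal(g$orientation_deg, ang, tolerance = 1e-9)
    expect_equal(g$wedge_deg, 0, tolerance = 1e-9)
  }
})

test_that("wedge angle equals the angle between the endplate lines", {
  # trapezoid: superior endplate sloped +3 deg, inferior sloped -3 deg;
  # oracle: angle between direction vectors (atan2 arithmetic) = 6 deg
  s <- tan(3 * pi / 180)
  lm <- tibble::tibble(
    patient_id = "p", visit = 1L, view = "standing", level = "T5",
    corner = c("SL", "SR", "IR", "IL"),
    x = c(-20, 20, 20, -20),
    y = c(10 - 20 * s, 10 + 20 * s, -10 - 20 * s, -10 + 20 * s))
  g <- vertebra_geometry(lm)
  expect_equal(g$wedge_deg, 6, tolerance = 1e-9)
})

test_that("square vertebrae fall back to the superior endplate and are flagged", {
  g <- vertebra_geometry(rect_vertebra(w = 30, h = 30, angle_deg = 10))
  expect_true(g$isotropic)
  expect_equal(g$orientation_deg, 10, tolerance = 1e-9)
})

test_that("degenerate (zero-area) vertebrae are a geometry error", {
  lm <- rect_vertebra()
  lm$y <- 0
  expect_error(vertebra_geometry(lm), "zero area")
})

test_that("normalize_coordinates is idempotent and flips y-down pixels", {
  sim <- generate_spine_landmarks(spine_sim_config(cobb = 30, seed = 1))
  expect_identical(normalize_coordinates(sim$landmarks), sim$landmarks)
  h <- 1000
  pix <- sim$landmarks
  pix$y <- h - pix$y
  back <- normalize_coordinates(pix, y_down = TRUE, image_height = h)
  expect_equal(back$y, sim$landmarks$y)
  # mislabelled corners (superior caudal to inferior) are rejected
  expect_error(normalize_coordinates(pix),
               "superior corners are not cranial")
  expect_error(normalize_coordinates(sim$landmarks, y_down = TRUE),
               "image_height")
})

test_that("spine curve requires >= 4 strictly monotone centroids", {
  g3 <- vertebra_geometry(stacked_spine(3))
  expect_error(fit_spine_curve(g3), "at least 4")
  g <- vertebra_geometry(stacked_spine(5))
  g$centroid_y[2] <- g$centroid_y[3]
  expect_error(fit_spine_curve(g), "monotone")
})

test_that("collinear centroids give a straight spline with no extrema", {
  curve <- fit_spine_curve(vertebra_geometry(stacked_spine(6)))
  expect_equal(nrow(curve$extrema), 0)
  expect_equal(nrow(find_apices(curve)), 0)
})

test_that("spline extrema land at the generating function's argmax", {
  # single sine bump: analytic extremum at mid-height
  cfg <- spine_sim_config(cobb = 40, length = 800, seed = 1)
  sim <- generate_spine_landmarks(cfg)
  curve <- fit_spine_curve(vertebra_geometry(sim$landmarks))
  expect_equal(nrow(curve$extrema), 1)
  expect_equal(curve$extrema$y, 400, tolerance = 1)
  # s-curve: two extrema of opposite deviation sign
  sim2 <- generate_spine_landmarks(
    spine_sim_config(cobb = 45, cobb2 = 45, shape = "s-curve", seed = 1))
  curve2 <- fit_spine_curve(vertebra_geometry(sim2$landmarks))
  expect_equal(nrow(curve2$extrema), 2)
  expect_equal(sort(sign(curve2$extrema$deviation)), c(-1, 1))
})

test_that("apices are the nearest centroids to qualifying extrema", {
  sim <- generate_spine_landmarks(spine_sim_config(cobb = 40, seed = 2))
  curve <- fit_spine_curve(vertebra_geometry(sim$landmarks))
  apices <- find_apices(curve)
  expect_equal(apices$level, sim$truth$apex_level)  # T9, middle of 17
  # nearest-centroid brute force
  d <- sqrt((curve$centroids$x - apices$extremum_x)^2 +
              (curve$centroids$y - apices$extremum_y)^2)
  expect_equal(apices$level, curve$centroids$level[which.min(d)])
})

test_that("measure_curve implements the Cobb arithmetic and tie rules", {
  # upper tilt +20, lower tilt -25 -> Cobb 45
  tilts <- c(20, 10, 0, -15, -25)
  m <- measure_curve(vertebra_geometry(stacked_spine(5, tilt = tilts)), "T3")
  expect_equal(m$cobb_deg, 45)
  expect_equal(m$upper_end, "T1")
  expect_equal(m$lower_end, "T5")
  expect_equal(m$levels, 5L)
  # all orientations zero: ends adjacent to the apex, 3 levels involved
  m0 <- measure_curve(vertebra_geometry(stacked_spine(5)), "T3")
  expect_equal(m0$cobb_deg, 0)
  expect_equal(m0$upper_end, "T2")
  expect_equal(m0$lower_end, "T4")
  expect_equal(m0$levels, 3L)
  # apex at the boundary is an error
  expect_error(measure_curve(vertebra_geometry(stacked_spine(5)), "T1"),
               "boundary")
})

test_that("measured Cobb recovers the generating angle within 2 degrees", {
  for (th in seq(10, 90, by = 10)) {
    sim <- generate_spine_landmarks(spine_sim_config(cobb = th, seed = 1))
    m <- measure_all(sim$landmarks)
    expect_equal(nrow(m), 1)
    expect_lt(abs(m$cobb_deg - th), 2)
    expect_equal(m$apex, sim$truth$apex_level)
  }
})

test_that("straight synthetic spines yield no curves", {
  sim <- generate_spine_landmarks(spine_sim_config(cobb = 0, seed = 1))
  expect_equal(nrow(measure_all(sim$landmarks)), 0)
})

test_that("the greater of two curves is flagged major", {
  sim <- generate_spine_landmarks(
    spine_sim_config(cobb = 50, cobb2 = 35, shape = "s-curve", seed = 2))
  m <- measure_all(sim$landmarks)
  expect_equal(nrow(m), 2)
  expect_true(m$major[which.max(m$cobb_deg)])
  expect_equal(sum(m$major), 1L)
  # upper (thoracic) curve is the 50-degree one by construction
  expect_equal(m$apex[m$major], sim$truth$curves$upper$apex_level)
  # curves share the junction end vertebra and have opposite sidedness
  expect_equal(m$lower_end[1], m$upper_end[2])
  expect_setequal(m$side, c("left", "right"))
})

test_that("Cobb and wedge are invariant to rigid motion and scale", {
  sim <- generate_spine_landmarks(spine_sim_config(cobb = 35, seed = 3))
  base <- measure_all(sim$landmarks)
  moved <- transform_landmarks(sim$landmarks, angle_deg = 0, dx = 512,
                               dy = -213, scale = 2.5)
  m2 <- measure_all(moved)
  expect_equal(m2$cobb_deg, base$cobb_deg, tolerance = 1e-6)
  expect_equal(m2$apex, base$apex)
  # small global rotations keep the ordering valid; Cobb must not move
  for (phi in c(-4, 3)) {
    rot <- transform_landmarks(sim$landmarks, angle_deg = phi)
    mr <- measure_all(rot)
    expect_equal(mr$cobb_deg, base$cobb_deg, tolerance = 1e-6)
  }
  wg <- vertebra_geometry(transform_landmarks(sim$landmarks, angle_deg = 3))
  expect_equal(wg$wedge_deg, vertebra_geometry(sim$landmarks)$wedge_deg,
               tolerance = 1e-6)
})

test_that("mirror reflection preserves Cobb and flips sidedness", {
  sim <- generate_spine_landmarks(spine_sim_config(cobb = 42, seed = 4))
  base <- measure_all(sim$landmarks)
  mir <- measure_all(mirror_landmarks(sim$landmarks))
  expect_equal(mir$cobb_deg, base$cobb_deg, tolerance = 1e-9)
  expect_true(base$side != mir$side)
})

test_that("landmark noise degrades Cobb accuracy monotonically on average", {
  err_at <- function(sd) {
    errs <- purrr::map_dbl(1:6, function(s) {
      sim <- generate_spine_landmarks(
        spine_sim_config(cobb = 40, noise_sd = sd, seed = s))
      m <- measure_all(sim$landmarks)
      maj <- m[m$major, ]
      if (nrow(maj) == 0) return(40)
      abs(maj$cobb_deg - 40)
    })
    mean(errs)
  }
  e <- c(err_at(0), err_at(1.5), err_at(4))
  expect_true(all(diff(e) >= 0))
})
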