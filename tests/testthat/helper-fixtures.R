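# Shared fixture builders (all fixtures are generated in code).

# One vertebra as a landmark tibble: an axis-aligned w x h rectangle
# centred at (cx, cy), rigidly rotated by angle_deg about its centre.
rect_vertebra <- function(level = "T5", cx = 0, cy = 0, w = 40, h = 20,
                          angle_deg = 0, patient_id = "p", visit = 1L,
                          view = "standing") {
  a <- angle_deg * pi / 180
  base <- rbind(SL = c(-w / 2, h / 2), SR = c(w / 2, h / 2),
                IR = c(w / 2, -h / 2), IL = c(-w / 2, -h / 2))
  rot <- base %*% t(matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2,
                           byrow = TRUE))
  tibble::tibble(patient_id = patient_id, visit = visit, view = view,
                 level = level, corner = rownames(base),
                 x = rot[, 1] + cx, y = rot[, 2] + cy)
}

# A straight vertical stack of n rectangles, optionally tilted per-vertebra.
stacked_spine <- function(n = 5, tilt = rep(0, n), spacing = 50,
                          levels = spinal_levels()[seq_len(n)]) {
  purrr::map_dfr(seq_len(n), function(i) {
    rect_vertebra(level = levels[i], cx = 0, cy = -spacing * (i - 1),
                  angle_deg = tilt[i])
  })
}

# Mirror a landmark table about a vertical axis, relabelling left/right
# corners so the table stays a valid acquisition of the mirrored patient.
mirror_landmarks <- function(landmarks, axis_x = 0) {
  out <- landmarks
  out$x <- 2 * axis_x - out$x
  swap <- c(SL = "SR", SR = "SL", IR = "IL", IL = "IR")
  out$corner <- unname(swap[out$corner])
  out
}

# Apply a global rigid motion (rotation in degrees, then translation).
transform_landmarks <- function(landmarks, angle_deg = 0, dx = 0, dy = 0,
                                scale = 1) {
  a <- angle_deg * pi / 180
  x <- landmarks$x * scale
  y <- landmarks$y * scale
  out <- landmarks
  out$x <- x * cos(a) - y * sin(a) + dx
  out$y <- x * sin(a) + y * cos(a) + dy
  out
}

# A minimal valid raw cohort record.
one_record <- function(...) {
  rec <- tibble::tibble(
    patient_id = "P0001",
    initial_lumbar_lordosis_angle = 53.6,
    initial_thoracic_kyphosis_angle = 24.2,
    age_at_first_visit = 12.5,
    age_at_last_visit = 13.5,
    time_span = 1,
    apex_wedge_angle = 6,
    lenke_type = 1L,
    flexibility = 57,
    apex_axial_rotation = 21,
    initial_major_cobb_angle = 48,
    brace_status = "brace",
    gender = "F",
    number_of_levels_involved = 7L,
    apex_location = "T8",
    risser_plus_stage = "0-",
    final_major_cobb = 58)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}
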