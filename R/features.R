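#' Curve flexibility from standing and bending Cobb angles
#'
#' Flexibility is the percentage reduction of the Cobb angle from the
#' standing to the side-bending radiograph:
#' `100 * (standing - bending) / standing`, clipped to \[0, 100\]. A
#' bending Cobb larger than the standing Cobb is clinically implausible
#' and triggers a warning before clipping to 0.
#'
#' @param standing_cobb Standing Cobb angle(s), degrees; must be > 0.
#' @param bending_cobb Side-bending Cobb angle(s), degrees; must be >= 0.
#' @return Flexibility in percent, same length as the inputs.
#' @export
#' @examples
#' flexibility(60, 30)  # 50
#' flexibility(50, 0)   # 100
flexibility <- function(standing_cobb, bending_cobb) {
  if (any(standing_cobb <= 0)) {
    stop("standing Cobb angle must be positive", call. = FALSE)
  }
  if (any(bending_cobb < 0)) {
    stop("bending Cobb angle must be non-negative", call. = FALSE)
  }
  f <- 100 * (standing_cobb - bending_cobb) / standing_cobb
  if (any(f < 0)) {
    warning("bending Cobb exceeds standing Cobb; flexibility clipped to 0",
            call. = FALSE)
  }
  pmin(pmax(f, 0), 100)
}

#' Structural-curve rule
#'
#' A minor curve is structural when its Cobb angle is at least 80% of the
#' major curve's (boundary inclusive).
#'
#' @param major_cobb,minor_cobb Cobb angles in degrees; `minor_cobb` must
#'   not exceed `major_cobb` (otherwise the caller has mislabelled the
#'   curves).
#' @param threshold Structural fraction, default 0.8.
#' @return Logical.
#' @export
#' @examples
#' is_structural(50, 40)    # TRUE (boundary inclusive)
#' is_structural(50, 39.9)  # FALSE
is_structural <- function(major_cobb, minor_cobb, threshold = 0.8) {
  if (any(minor_cobb > major_cobb)) {
    stop("minor Cobb exceeds major Cobb: curves are mislabelled",
         call. = FALSE)
  }
  if (any(minor_cobb <= 0)) {
    stop("minor Cobb must be positive", call. = FALSE)
  }
  minor_cobb >= threshold * major_cobb
}

#' Curve region from the apex level
#'
#' Maps an apical level to the three coronal curve regions used by the
#' modified Lenke classification. Default bands: T2-T5 proximal thoracic,
#' T6-T11 main thoracic, T12-L4 thoracolumbar/lumbar (configurable).
#'
#' @param apex_level Character vector of apex levels (T1..T12, L1..L5).
#' @param bands Named list giving the inclusive cranial/caudal boundary of
#'   each band.
#' @return Character vector in
#'   `c("proximal-thoracic", "main-thoracic", "thoracolumbar/lumbar")`.
#' @export
#' @examples
#' curve_region(c("T8", "L2", "T12"))
curve_region <- function(apex_level,
                         bands = list(`proximal-thoracic` = c("T2", "T5"),
                                      `main-thoracic` = c("T6", "T11"),
                                      `thoracolumbar/lumbar` = c("T12", "L4"))) {
  idx <- level_index(apex_level)
  if (any(!is_standard_level(apex_level))) {
    stop("apex level must be a standard level T1..L5", call. = FALSE)
  }
  out <- rep(NA_character_, length(idx))
  for (region in names(bands)) {
    lo <- level_index(bands[[region]][1])
    hi <- level_index(bands[[region]][2])
    out[idx >= lo & idx <= hi] <- region
  }
  if (anyNA(out)) {
    stop("apex level(s) outside the classification bands: ",
         paste(unique(apex_level[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Modified Lenke curve type
#'
#' Classifies a patient's set of measured curves into the six modified
#' Lenke types from the regions of the structural curves:
#' \describe{
#'   \item{1}{main thoracic only}
#'   \item{2}{double thoracic (proximal + main thoracic)}
#'   \item{3}{double major, thoracic curve > lumbar curve}
#'   \item{4}{triple major (all three regions)}
#'   \item{5}{thoracolumbar/lumbar only}
#'   \item{6}{double major, thoracolumbar/lumbar curve > thoracic curve}
#' }
#' The major curve (greatest Cobb) is always structural. A structural-curve
#' pattern matching none of the six rules (e.g. proximal thoracic alone) is
#' an explicit error, never a silent default. Equal main-thoracic and
#' lumbar Cobb angles classify as type 3.
#'
#' @param curves Tibble with one row per curve and columns `apex`
#'   (level label), `cobb_deg`, and either `structural` (logical) or
#'   `major` (logical; structural flags are then derived with
#'   [is_structural()]).
#' @return Integer scalar in 1..6.
#' @export
#' @examples
#' mlenke_type(tibble::tibble(apex = "T8", cobb_deg = 50, major = TRUE))
mlenke_type <- function(curves) {
  stopifnot(nrow(curves) >= 1)
  if (!"structural" %in% names(curves)) {
    if (!"major" %in% names(curves)) {
      stop("curves need a 'structural' or 'major' column", call. = FALSE)
    }
    if (sum(curves$major) != 1) {
      stop("exactly one curve must be flagged major", call. = FALSE)
    }
    major_cobb <- curves$cobb_deg[curves$major]
    curves$structural <- curves$major |
      is_structural(major_cobb, pmin(curves$cobb_deg, major_cobb))
  }
  st <- curves[curves$structural, , drop = FALSE]
  if (nrow(st) == 0) stop("no structural curve", call. = FALSE)
  st$region <- curve_region(st$apex)
  regions <- unique(st$region)
  has <- function(r) r %in% regions
  pt <- "proximal-thoracic"; mt <- "main-thoracic"; tl <- "thoracolumbar/lumbar"
  cobb_in <- function(r) max(st$cobb_deg[st$region == r])
  type <-
    if (setequal(regions, mt)) 1L
    else if (setequal(regions, c(pt, mt))) 2L
    else if (setequal(regions, c(pt, mt, tl))) 4L
    else if (setequal(regions, tl)) 5L
    else if (setequal(regions, c(mt, tl))) {
      if (cobb_in(mt) >= cobb_in(tl)) 3L else 6L
    } else NA_integer_
  if (is.na(type)) {
    stop("unclassifiable structural-curve pattern: {",
         paste(sort(regions), collapse = ", "),
         "} matches no modified Lenke type", call. = FALSE)
  }
  type
}

risser_vocabulary <- c("0-", "0+", "1", "2", "3", "3/4", "4", "5")

#' Encode the Risser "+" skeletal-maturity grade
#'
#' The eight-grade Risser "+" scale augments the classical Risser score
#' with triradiate-cartilage status: `0-` (open triradiate cartilage),
#' `0+` (closed), `1` (0-25% iliac apophysis coverage), `2` (25-50%),
#' `3` (50-75%), `3/4` (75-100%), `4` (start of fusion), `5` (complete
#' fusion). Grades map to the ordinals 0..7 in that order.
#'
#' @param grade Character vector of grades (whitespace-tolerant).
#' @return Integer ordinals 0..7.
#' @export
#' @examples
#' encode_risser_plus(c("0-", "3/4", "5"))
encode_risser_plus <- function(grade) {
  code <- match(trimws(as.character(grade)), risser_vocabulary) - 1L
  if (anyNA(code)) {
    stop("unknown Risser \"+\" grade(s): ",
         paste(unique(grade[is.na(code)]), collapse = ", "),
         "; vocabulary is ", paste(risser_vocabulary, collapse = ", "),
         call. = FALSE)
  }
  code
}

#' The model feature table
#'
#' The fixed index-to-feature mapping of the 15 model input features. The
#' index order is used everywhere a feature subset is reported.
#'
#' @return Tibble with `index` (0-based), `column` (the cohort-table column
#'   name), and `type` (`"continuous"`, `"nominal"` or `"ordinal"`).
#' @export
feature_table <- function() {
  tibble::tribble(
    ~index, ~column,                           ~type,
    0L,     "initial_lumbar_lordosis_angle",   "continuous",
    1L,     "initial_thoracic_kyphosis_angle", "continuous",
    2L,     "age_at_first_visit",              "continuous",
    3L,     "age_at_last_visit",               "continuous",
    4L,     "time_span",                       "continuous",
    5L,     "apex_wedge_angle",                "continuous",
    6L,     "lenke_type",                      "nominal",
    7L,     "flexibility",                     "continuous",
    8L,     "apex_axial_rotation",             "continuous",
    9L,     "initial_major_cobb_angle",        "continuous",
    10L,    "brace_status",                    "nominal",
    11L,    "gender",                          "nominal",
    12L,    "number_of_levels_involved",       "ordinal",
    13L,    "apex_location",                   "ordinal",
    14L,    "risser_plus_stage",               "ordinal")
}

gender_codes <- c("F" = 0, "M" = 1)
brace_codes <- c("no-brace" = 0, "brace" = 1)

normalize_gender <- function(x) {
  x <- toupper(substr(trimws(x), 1, 1))
  if (any(!x %in% c("F", "M"))) {
    stop("gender must be F/Female or M/Male", call. = FALSE)
  }
  x
}

normalize_brace <- function(x) {
  x <- tolower(gsub("[ _]", "-", trimws(x)))
  if (any(!x %in% names(brace_codes))) {
    stop("brace status must be 'brace' or 'no-brace'", call. = FALSE)
  }
  x
}

#' Encode a cohort table into the numeric model feature matrix
#'
#' Turns raw, human-readable patient records into the 15-column numeric
#' feature matrix the models consume, preserving the [feature_table()]
#' column order. Encodings: gender F -> 0, M -> 1; brace status
#' no-brace -> 0, brace -> 1; Lenke type kept as its integer label 1..6;
#' apex location as the cranio-caudal ordinal (T1 -> 0 ... L5 -> 16);
#' Risser "+" via [encode_risser_plus()]; continuous features pass through
#' unchanged. Records with missing fields are rejected (the pipeline is
#' complete-case; no imputation).
#'
#' @param cohort A validated cohort tibble (see [read_cohort()]) with the
#'   [feature_table()] columns plus, optionally, `final_major_cobb`.
#' @return Tibble of 15 numeric feature columns (plus `final_major_cobb`
#'   when present) in feature-index order.
#' @export
#' @examples
#' coh <- generate_cohort(n = 5, seed = 1)
#' encode_cohort(coh)
encode_cohort <- function(cohort) {
  ft <- feature_table()
  missing_cols <- setdiff(ft$column, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(cohort[, ft$column])) {
    bad <- which(rowSums(is.na(cohort[, ft$column])) > 0)
    stop("missing values in record(s) ", paste(bad, collapse = ", "),
         "; records with missing fields are rejected (no imputation)",
         call. = FALSE)
  }
  out <- tibble::tibble(
    initial_lumbar_lordosis_angle = as.numeric(cohort$initial_lumbar_lordosis_angle),
    initial_thoracic_kyphosis_angle = as.numeric(cohort$initial_thoracic_kyphosis_angle),
    age_at_first_visit = as.numeric(cohort$age_at_first_visit),
    age_at_last_visit = as.numeric(cohort$age_at_last_visit),
    time_span = as.numeric(cohort$time_span),
    apex_wedge_angle = as.numeric(cohort$apex_wedge_angle),
    lenke_type = as.numeric(cohort$lenke_type),
    flexibility = as.numeric(cohort$flexibility),
    apex_axial_rotation = as.numeric(cohort$apex_axial_rotation),
    initial_major_cobb_angle = as.numeric(cohort$initial_major_cobb_angle),
    brace_status = unname(brace_codes[normalize_brace(cohort$brace_status)]),
    gender = unname(gender_codes[normalize_gender(cohort$gender)]),
    number_of_levels_involved = as.numeric(cohort$number_of_levels_involved),
    apex_location = as.numeric(level_index(cohort$apex_location)),
    risser_plus_stage = as.numeric(encode_risser_plus(cohort$risser_plus_stage)))
  if ("final_major_cobb" %in% names(cohort)) {
    out$final_major_cobb <- as.numeric(cohort$final_major_cobb)
  }
  out
}

#' Decode an encoded feature matrix back to human-readable records
#'
#' Inverse of [encode_cohort()]; useful for round-tripping and for
#' presenting model inputs.
#'
#' @param encoded A tibble produced by [encode_cohort()].
#' @return A raw cohort tibble.
#' @export
decode_cohort <- function(encoded) {
  out <- encoded
  out$gender <- names(gender_codes)[match(encoded$gender, gender_codes)]
  out$brace_status <- names(brace_codes)[match(encoded$brace_status,
                                               brace_codes)]
  out$apex_location <- spinal_levels()[encoded$apex_location + 1]
  out$risser_plus_stage <- risser_vocabulary[encoded$risser_plus_stage + 1]
  out$lenke_type <- as.integer(encoded$lenke_type)
  out$number_of_levels_involved <- as.integer(encoded$number_of_levels_involved)
  out
}
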