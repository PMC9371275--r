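#' Spinal level vocabulary
#'
#' The standard coronal-view vocabulary runs cranio-caudally from T1 to L5
#' (17 levels). Densely resampled synthetic spines may instead carry generic
#' labels `V1..Vn`; those are accepted everywhere geometry only needs an
#' ordering, but not where a clinical level is required (apex encoding,
#' curve regions).
#'
#' @return Character vector of the 17 standard levels, cranial first.
#' @export
#' @examples
#' spinal_levels()
spinal_levels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

#' Cranio-caudal ordinal of a spinal level
#'
#' T1 maps to 0, T2 to 1, ..., L5 to 16 (the encoding used for the apex
#' location feature). Generic labels `V<k>` map to `k - 1`.
#'
#' @param level Character vector of level labels.
#' @return Integer ordinals (0-based).
#' @export
#' @examples
#' level_index(c("T1", "T8", "L5"))
level_index <- function(level) {
  level <- trimws(level)
  idx <- match(level, spinal_levels()) - 1L
  generic <- is.na(idx) & grepl("^V[0-9]+$", level)
  idx[generic] <- as.integer(sub("^V", "", level[generic])) - 1L
  if (anyNA(idx)) {
    stop("unknown spinal level(s): ",
         paste(unique(level[is.na(idx)]), collapse = ", "),
         "; expected T1..T12, L1..L5 (or generic V1..Vn)", call. = FALSE)
  }
  idx
}

#' @keywords internal
is_standard_level <- function(level) {
  trimws(level) %in% spinal_levels()
}

corner_order <- c("SL", "SR", "IR", "IL")

# Fan a single top-level seed out to per-stage seeds.  Fixed documented
# derivation so every stage is independently reproducible; kept well below
# .Machine$integer.max for small user seeds.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, spine = 151L, split = 202L, sbfs = 303L,
               grid = 404L, train = 505L, nulls = 606L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}
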