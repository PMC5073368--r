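# Bruise quantification: per-berry bruise ratio index, two-side averaging,
# threshold calling, and per-replicate bruised-fruit counts.

#' Bruise ratio of one berry
#'
#' Fraction of a berry's countable pixels classified as bruised. Calyx-
#' excluded pixels are removed from both numerator and denominator (removing
#' them only from the numerator would bias small berries downward).
#'
#' @param classified A `classified_image`.
#' @param berry_id Positive berry label.
#' @param drop_excluded_from_denominator If `FALSE`, excluded pixels stay in
#'   the denominator.
#' @return Fraction in `[0, 1]`.
#' @export
bruise_ratio <- function(classified, berry_id,
                         drop_excluded_from_denominator = TRUE) {
  stopifnot(inherits(classified, "classified_image"))
  sel <- classified$labelmap$labels == berry_id
  if (!any(sel)) stop("berry ", berry_id, " not present in the label map")
  cls <- classified$classes[sel]
  n_bruised <- sum(cls == 2L)
  denom <- if (drop_excluded_from_denominator) sum(cls != 3L) else length(cls)
  if (denom == 0L) stop("berry ", berry_id, " has no countable pixels")
  n_bruised / denom
}

#' Bruise ratios for all berries in a classified image
#'
#' @inheritParams bruise_ratio
#' @return Numeric vector indexed by berry id.
#' @export
bruise_ratios <- function(classified, drop_excluded_from_denominator = TRUE) {
  n <- nrow(classified$labelmap$centers)
  vapply(seq_len(n), bruise_ratio, numeric(1), classified = classified,
         drop_excluded_from_denominator = drop_excluded_from_denominator)
}

#' Two-side bruise ratio index
#'
#' When a fruit is imaged on both the stem and calyx sides, its bruise ratio
#' index is the arithmetic mean of the two per-side ratios.
#'
#' @param stem_ratio,calyx_ratio Per-side ratios in `[0, 1]` (vectorized).
#' @return Mean ratio in `[0, 1]`.
#' @export
two_side_ratio <- function(stem_ratio, calyx_ratio) {
  stopifnot(all(stem_ratio >= 0 & stem_ratio <= 1),
            all(calyx_ratio >= 0 & calyx_ratio <= 1))
  (stem_ratio + calyx_ratio) / 2
}

#' Call a fruit bruised from its bruise ratio index
#'
#' A fruit is bruised iff its index strictly exceeds the threshold (default
#' 0.2, i.e. 20 percent bruised area).
#'
#' @param ratio Bruise ratio index (or human assessment), vectorized.
#' @param threshold Calling threshold.
#' @return Logical vector.
#' @export
call_bruised <- function(ratio, threshold = 0.2) {
  stopifnot(all(ratio >= 0 & ratio <= 1))
  ratio > threshold
}

#' Count bruised fruit per replicate group
#'
#' @param ratios Numeric vector of per-fruit indices.
#' @param groups Factor/character replicate-group assignment, same length.
#' @param threshold Calling threshold passed to [call_bruised()].
#' @return Named integer vector of bruised counts per group.
#' @export
count_bruised <- function(ratios, groups, threshold = 0.2) {
  stopifnot(length(ratios) == length(groups))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) warning("empty replicate group; count is 0")
  counts <- tapply(call_bruised(ratios, threshold), groups, sum,
                   default = 0L)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Match berries between two images of the same tray
#'
#' Pairs each berry in `from_centers` with its nearest neighbor in
#' `to_centers` (the two images show the same physical tray, so component
#' centers nearly coincide). The assignment must be one-to-one; ambiguous
#' matches are an error.
#'
#' @param from_centers,to_centers N x 2 matrices of (row, col) centers.
#' @return Integer vector `m` such that berry `i` of `from` corresponds to
#'   berry `m[i]` of `to`.
#' @export
match_berries <- function(from_centers, to_centers) {
  stopifnot(nrow(from_centers) == nrow(to_centers))
  d2 <- outer(from_centers[, 1], to_centers[, 1], `-`)^2 +
    outer(from_centers[, 2], to_centers[, 2], `-`)^2
  m <- apply(d2, 1, which.min)
  if (anyDuplicated(m)) stop("berry matching is not one-to-one")
  as.integer(m)
}

#' Assemble a per-berry bruise report
#'
#' Pairs berries across the stem- and calyx-side images by the raster-scan
#' rank of their component centers (both sides image the same tray of
#' fruit), averages the two per-side ratios, and attaches optional firmness
#' and human-assessment columns.
#'
#' @param stem `classified_image` of the stem side.
#' @param calyx Optional `classified_image` of the calyx side (`NULL` for
#'   single-side imaging).
#' @param threshold Bruised-call threshold.
#' @param firmness Optional numeric vector (N/mm), one per berry.
#' @param human_assessment Optional numeric vector in `[0, 1]`.
#' @return `data.frame` with columns `berry_id`, `side`, `bruise_ratio`,
#'   `bruised`, and the optional measurements.
#' @export
bruise_report <- function(stem, calyx = NULL, threshold = 0.2,
                          firmness = NULL, human_assessment = NULL) {
  r_stem <- bruise_ratios(stem)
  if (is.null(calyx)) {
    ratio <- r_stem
    side <- "single"
  } else {
    r_calyx <- bruise_ratios(calyx)
    if (length(r_calyx) != length(r_stem)) {
      stop("stem and calyx images contain different numbers of berries")
    }
    ratio <- two_side_ratio(r_stem, r_calyx)
    side <- "both"
  }
  out <- data.frame(
    berry_id = seq_along(ratio),
    side = side,
    bruise_ratio = ratio,
    bruised = call_bruised(ratio, threshold)
  )
  if (!is.null(firmness)) out$firmness <- firmness
  if (!is.null(human_assessment)) out$human_assessment <- human_assessment
  out
}
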