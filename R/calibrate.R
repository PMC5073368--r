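#' Flat-field reflectance calibration
#'
#' Converts raw digital numbers to reflectance against white and dark
#' reference cubes: per pixel and band,
#' \deqn{R = (S - D) / (W - D)}
#' which removes illumination non-uniformity and pixel-to-pixel sensitivity
#' variation. Pixels where the white and dark references coincide are
#' uninformative; they are set to 0 and counted in a warning.
#'
#' @param raw,white,dark `hypercube`s of identical shape and grid. `white`
#'   and `dark` are the reference cubes (already averaged if acquired as
#'   multiple frames).
#' @param clip_max Upper clip for the reflectance (specular pixels can
#'   exceed 1); default 2.
#' @return A reflectance `hypercube`, values clipped to `[0, clip_max]`.
#' @export
flat_field_correct <- function(raw, white, dark, clip_max = 2) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data))) {
    stop("raw, white and dark cubes must have identical dimensions")
  }
  if (!identical(raw$grid$values, white$grid$values) ||
      !identical(raw$grid$values, dark$grid$values)) {
    stop("raw, white and dark cubes must share the wavelength grid")
  }
  denom <- white$data - dark$data
  bad <- denom <= 0
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(sprintf("%d pixel/band cells have white <= dark; set to 0", n_bad))
    denom[bad] <- 1
  }
  r <- (raw$data - dark$data) / denom
  r[bad] <- 0
  r[r < 0] <- 0
  r[r > clip_max] <- clip_max
  hypercube(r, raw$grid, kind = "reflectance")
}

#' Threshold a band image into a binary mask
#'
#' Foreground is strictly greater than the level. The segmentation
#' thresholds of the reference protocol (737 and 942) are on the raw 12-bit
#' DN scale at the 1075 nm band, where berry/background contrast peaks.
#'
#' @param band_image Numeric matrix (one band of a cube).
#' @param level_dn Threshold level, same scale as `band_image`.
#' @return Integer 0/1 matrix of the same shape.
#' @export
threshold_mask <- function(band_image, level_dn) {
  stopifnot(is.matrix(band_image), is.numeric(level_dn))
  mask <- (band_image > level_dn) * 1L
  storage.mode(mask) <- "integer"
  mask
}
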