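#' Create a hyperspectral cube
#'
#' A `hypercube` bundles a rows x cols x bands array with its wavelength
#' grid and a `kind` tag recording where it sits in the calibration chain.
#' Raw and reference cubes carry digital numbers (DN) on the camera's 12-bit
#' scale (0-4095); calibrated cubes carry dimensionless reflectance.
#'
#' @param data Numeric 3-D array, dimensions rows x cols x bands.
#' @param grid A `wavelength_grid` whose length equals `dim(data)[3]`.
#' @param kind One of `"raw"`, `"white_ref"`, `"dark_ref"`, `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, grid, kind = c("raw", "white_ref", "dark_ref",
                                           "reflectance")) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(grid, "wavelength_grid"))
  if (dim(data)[3] != length(grid$values)) {
    stop(sprintf("cube has %d bands but grid has %d wavelengths",
                 dim(data)[3], length(grid$values)))
  }
  if (kind != "reflectance") {
    rng <- range(data)
    if (rng[1] < 0 || rng[2] > 4095) {
      stop("DN cube values must lie in [0, 4095]")
    }
  } else if (any(!is.finite(data)) || min(data) < 0) {
    stop("reflectance cube must be finite and non-negative")
  }
  structure(list(data = data, grid = grid, kind = kind), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%g-%g nm), kind=%s\n",
              d[1], d[2], d[3], x$grid$values[1],
              x$grid$values[length(x$grid$values)], x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Extract one band of a cube as a matrix
#'
#' @param cube A `hypercube`.
#' @param wavelength_nm Band center to extract (nearest-band lookup).
#' @return rows x cols numeric matrix.
#' @export
band_image <- function(cube, wavelength_nm) {
  stopifnot(inherits(cube, "hypercube"))
  cube$data[, , band_index(cube$grid, wavelength_nm)]
}
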