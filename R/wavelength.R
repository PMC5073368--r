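#' Construct a uniform wavelength grid
#'
#' Builds the ordered set of band-center wavelengths for a hyperspectral
#' sensor with a uniform spectral interval, e.g. the 141-band 950-1650 nm
#' grid of a 5 nm NIR imager.
#'
#' @param start_nm First band center in nanometres.
#' @param end_nm Last band center in nanometres; must exceed `start_nm`.
#' @param step_nm Spectral interval in nanometres.
#' @return An object of class `wavelength_grid`: a list with `start_nm`,
#'   `step_nm` and `values` (band centers, strictly increasing, both
#'   endpoints included).
#' @examples
#' g <- make_wavelength_grid(950, 1650, 5)
#' length(g$values)  # 141
#' @export
make_wavelength_grid <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (end_nm <= start_nm) stop("end_nm must be greater than start_nm")
  if (step_nm <= 0) stop("step_nm must be positive")
  span <- end_nm - start_nm
  n_steps <- span / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop(sprintf(
      "wavelength range %g-%g nm is not divisible by the %g nm interval",
      start_nm, end_nm, step_nm
    ))
  }
  values <- start_nm + step_nm * seq.int(0L, round(n_steps))
  structure(
    list(start_nm = start_nm, step_nm = step_nm, values = values),
    class = "wavelength_grid"
  )
}

#' Number of bands in a wavelength grid
#' @param x A `wavelength_grid`.
#' @param ... Ignored.
#' @export
length.wavelength_grid <- function(x) length(x$values)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %g-%g nm, step %g nm\n",
    length(x$values), x$values[1], x$values[length(x$values)], x$step_nm
  ))
  invisible(x)
}

#' Map a wavelength to its nearest band index
#'
#' Nearest-band lookup (no interpolation): returns the 1-based index of the
#' band center closest to `wavelength_nm`, ties broken toward the lower
#' index. Wavelengths more than half a step outside the grid are rejected.
#'
#' @param grid A `wavelength_grid`.
#' @param wavelength_nm Query wavelength in nanometres.
#' @return Integer band index (1-based).
#' @examples
#' g <- make_wavelength_grid(950, 1650, 5)
#' band_index(g, 1075)  # 26
#' @export
band_index <- function(grid, wavelength_nm) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(wavelength_nm),
            length(wavelength_nm) == 1L)
  v <- grid$values
  half <- grid$step_nm / 2
  if (wavelength_nm < v[1] - half || wavelength_nm > v[length(v)] + half) {
    stop(sprintf("wavelength %g nm outside grid range %g-%g nm",
                 wavelength_nm, v[1], v[length(v)]))
  }
  d <- abs(v - wavelength_nm)
  # which.min returns the first minimum, i.e. the lower index on ties
  as.integer(which.min(d))
}
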