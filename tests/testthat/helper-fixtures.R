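# Shared fixtures: everything is built in code at test time.

nir_grid <- make_wavelength_grid(950, 1650, 5)

# tiny cube with known values for I/O and calibration tests
tiny_cube <- function(rows = 4, cols = 5, bands = 3, kind = "raw",
                      seed = 42) {
  grid <- make_wavelength_grid(1000, 1000 + 10 * (bands - 1), 10)
  data <- local_seed(seed,
                     array(sample(0:4095, rows * cols * bands, replace = TRUE),
                           c(rows, cols, bands)))
  if (kind == "reflectance") data <- data / 4095
  hypercube(data, grid, kind = kind)
}

# compact phantom used where full 240 px scenes would be wasteful
small_phantom <- function(...) {
  phantom_config(rows = 120, cols = 120, n_berries = 9,
                 radius_range = c(12, 15), ...)
}

# small labeled library with controllable class separation (two Gaussian
# clouds), for classifier mechanics that do not need realistic spectra
point_cloud_library <- function(n_per_class = 40, n_bands = 8,
                                separation = 1, sigma = 0.05, seed = 7) {
  local_seed(seed, {
    healthy <- matrix(stats::rnorm(n_per_class * n_bands, 1, sigma),
                      n_per_class)
    bruised <- matrix(stats::rnorm(n_per_class * n_bands, 1 + separation,
                                   sigma), n_per_class)
    lib <- merge_libraries(
      hsibruise:::.new_spectral_library(
        healthy, rep("healthy", n_per_class),
        seq(1000, by = 10, length.out = n_bands), normalized = TRUE),
      hsibruise:::.new_spectral_library(
        bruised, rep("bruised", n_per_class),
        seq(1000, by = 10, length.out = n_bands), normalized = TRUE)
    )
    lib
  })
}
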