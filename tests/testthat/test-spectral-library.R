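test_that("ROI extraction yields one row per mask pixel in raster order", {
  cube <- tiny_cube(4, 4, 3, kind = "reflectance")
  mask <- matrix(0L, 4, 4)
  mask[1, 2] <- 1L; mask[2, 1] <- 1L; mask[3, 4] <- 1L
  lib <- extract_roi_spectra(cube, mask, "healthy")
  expect_identical(nrow(lib$spectra), 3L)
  # raster (row-major) order: (1,2), (2,1), (3,4)
  expect_equal(lib$spectra[1, ], cube$data[1, 2, ])
  expect_equal(lib$spectra[2, ], cube$data[2, 1, ])
  expect_equal(lib$spectra[3, ], cube$data[3, 4, ])

  expect_error(extract_roi_spectra(cube, matrix(0L, 4, 4), "healthy"),
               "empty")
  expect_error(extract_roi_spectra(cube, matrix(1L, 5, 5), "healthy"),
               "dimensions")
  raw <- tiny_cube(4, 4, 3, kind = "raw")
  expect_error(extract_roi_spectra(raw, mask, "healthy"), "calibrated")
})

test_that("mean normalization has the stated algebraic properties", {
  expect_equal(normalize_spectra(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_spectra(c(1, 2, 3)), c(0.5, 1, 1.5))

  x <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(normalize_spectra(3.7 * x), normalize_spectra(x))
  expect_equal(normalize_spectra(normalize_spectra(x)),
               normalize_spectra(x))

  expect_error(normalize_spectra(c(0, 0, 0)), "mean")
})

test_that("SNV normalization centers and scales each spectrum", {
  x <- matrix(runif(30), 5)
  s <- normalize_spectra(x, method = "snv")
  expect_equal(rowMeans(s), rep(0, 5))
  expect_equal(apply(s, 1, sd), rep(1, 5))
  expect_error(normalize_spectra(matrix(1, 2, 4), method = "snv"),
               "constant")
})

test_that("balancing subsamples the majority class reproducibly", {
  lib <- point_cloud_library(n_per_class = 100)
  drop <- which(lib$class_labels == "bruised")[1:40]
  lib$spectra <- lib$spectra[-drop, ]
  lib$class_labels <- lib$class_labels[-drop]

  bal <- balance_library(lib, seed = 11)
  expect_identical(as.vector(table(bal$class_labels)), c(60L, 60L))
  # minority rows all kept
  expect_true(all(lib$spectra[lib$class_labels == "bruised", ] %in%
                    bal$spectra))
  # no duplicated rows
  expect_identical(anyDuplicated(bal$spectra), 0L)
  # determinism under the seed
  bal2 <- balance_library(lib, seed = 11)
  expect_identical(bal$spectra, bal2$spectra)
  # already balanced input is returned unchanged
  expect_identical(balance_library(bal, seed = 3)$spectra, bal$spectra)

  one_class <- lib
  one_class$spectra <- lib$spectra[lib$class_labels == "healthy", ]
  one_class$class_labels <- lib$class_labels[lib$class_labels == "healthy"]
  expect_error(balance_library(one_class), "both classes")
})

test_that("merging preserves rows, labels and balance", {
  a <- point_cloud_library(n_per_class = 30, seed = 1)
  b <- point_cloud_library(n_per_class = 50, seed = 2)
  m <- merge_libraries(a, b)
  expect_identical(nrow(m$spectra), 160L)
  expect_identical(as.vector(table(m$class_labels)), c(80L, 80L))
  expect_equal(m$spectra[1:60, ], a$spectra)

  empty <- a
  empty$spectra <- a$spectra[0, , drop = FALSE]
  empty$class_labels <- a$class_labels[0]
  expect_identical(merge_libraries(a, empty)$spectra, a$spectra)

  c_ <- point_cloud_library(n_per_class = 10, n_bands = 5)
  expect_error(merge_libraries(a, c_), "grids")
})

test_that("two balanced libraries of the reported sizes merge to the reported per-class total", {
  # library row counts are the quantities of interest; band count is small
  mk <- function(n_total, seed) {
    half <- n_total / 2
    local_seed(seed, hsibruise:::.new_spectral_library(
      matrix(stats::rnorm(n_total * 4), n_total),
      rep(c("healthy", "bruised"), each = half),
      c(1000, 1010, 1020, 1030)))
  }
  m <- merge_libraries(mk(28352, 1), mk(61580, 2))
  expect_identical(sum(m$class_labels == "bruised"), 44966L)
  expect_identical(sum(m$class_labels == "healthy"), 44966L)
})

test_that("library CSV round trip preserves spectra and labels", {
  lib <- point_cloud_library(n_per_class = 5)
  path <- file.path(withr::local_tempdir(), "lib.csv")
  write_library_csv(lib, path)
  back <- read_library_csv(path, normalized = TRUE)
  expect_equal(unname(back$spectra), unname(lib$spectra), tolerance = 1e-12)
  expect_identical(as.character(back$class_labels),
                   as.character(lib$class_labels))
  expect_equal(back$wavelengths, lib$wavelengths)
})

test_that("phantom ROI spectra sit nearer their own class mean", {
  cfg <- small_phantom()
  sc <- make_scene(cfg, "fully_bruised", seed = 9)
  refl <- suppressWarnings(flat_field_correct(sc$raw, sc$white, sc$dark))
  roi <- sc$truth$bruise_mask
  lib <- extract_roi_spectra(refl, roi, "bruised")
  g <- make_wavelength_grid(950, 1650, 5)
  h <- healthy_spectrum(g); b <- bruised_spectrum(g)
  d_h <- sqrt(rowSums(sweep(lib$spectra, 2, h)^2))
  d_b <- sqrt(rowSums(sweep(lib$spectra, 2, b)^2))
  # the tissue model deliberately mixes partially-bruised pixels into the
  # bruise region, so a minority of rows sit nearer the healthy mean; the
  # bulk and the library mean must side with the bruised reference
  expect_gt(mean(d_b < d_h), 0.75)
  mu <- colMeans(lib$spectra)
  expect_lt(sum((mu - b)^2), sum((mu - h)^2))
})
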