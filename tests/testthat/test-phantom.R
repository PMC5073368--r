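test_that("reference tissue spectra show the NIR water-absorption shape", {
  g <- nir_grid
  h <- healthy_spectrum(g)
  b <- bruised_spectrum(g)
  at <- function(s, wl) s[band_index(g, wl)]

  # healthy reflectance turns upward again past the 1470 nm global minimum
  expect_gt(at(h, 1650), at(h, 1470))
  # bruised tissue stays flat between 1470 and 1650 nm
  expect_lt(abs(at(b, 1650) - at(b, 1470)), 0.02)
  # healthy tissue reflects at least as much as bruised at every band
  expect_true(all(h >= b))
  # 1470 nm is the global minimum for both tissues
  expect_identical(band_index(g, g$values[which.min(h)]), band_index(g, 1470))
  expect_identical(band_index(g, g$values[which.min(b)]), band_index(g, 1470))
  # local dips at the other two water bands
  for (wl in c(980, 1200)) {
    i <- band_index(g, wl)
    expect_lt(h[i], h[i - 6])
    expect_lt(h[i], h[i + 6])
  }
})

test_that("scenes are deterministic and respect the DN contract", {
  cfg <- small_phantom()
  s1 <- make_scene(cfg, "steel60", seed = 7)
  s2 <- make_scene(cfg, "steel60", seed = 7)
  expect_identical(s1$raw$data, s2$raw$data)
  expect_identical(s1$truth$bruise_mask, s2$truth$bruise_mask)

  s3 <- make_scene(cfg, "steel60", seed = 8)
  expect_false(identical(s1$raw$data, s3$raw$data))

  expect_true(all(s1$raw$data >= 0 & s1$raw$data <= 4095))
  expect_true(all(s1$white$data >= s1$dark$data))
  # white exceeds raw except where noise pushes a pixel above the panel
  expect_gt(mean(s1$white$data >= s1$raw$data), 0.999)
})

test_that("treatments set the true bruise fractions by construction", {
  cfg <- small_phantom()
  ctrl <- make_scene(cfg, "control", seed = 2)
  expect_true(all(ctrl$truth$true_fraction == 0))
  expect_true(all(ctrl$truth$severity == 0))

  full <- make_scene(cfg, "fully_bruised", seed = 2)
  expect_true(all(full$truth$severity >= 0.8))
  expect_gte(mean(full$truth$true_fraction), 0.85)

  # numeric treatments set the mean fraction directly
  mid <- make_scene(cfg, 0.4, seed = 2)
  expect_lt(abs(mean(mid$truth$severity) - 0.4), 0.06)
})

test_that("bruise masks sit inside berries and match their stated fraction", {
  cfg <- small_phantom()
  sc <- make_scene(cfg, "steel60", seed = 3)
  expect_true(all(sc$truth$labels[sc$truth$bruise_mask == 1L] > 0L))
  # recompute the calyx-excluded fraction independently
  for (k in c(1, 5, 9)) {
    idx <- which(sc$truth$labels == k)
    rr <- (idx - 1L) %% nrow(sc$truth$labels) + 1L
    cc <- (idx - 1L) %/% nrow(sc$truth$labels) + 1L
    keep <- (rr - sc$truth$centers[k, 1])^2 +
      (cc - sc$truth$centers[k, 2])^2 > 25
    f <- sum(sc$truth$bruise_mask[idx][keep]) / sum(keep)
    expect_equal(f, sc$truth$true_fraction[k])
  }
})

test_that("stem side carries more severe bruising than the calyx side", {
  cfg <- small_phantom()
  stem <- make_scene(cfg, "steel60", seed = 4, side = "stem")
  calyx <- make_scene(cfg, "steel60", seed = 4, side = "calyx")
  expect_identical(stem$truth$centers, calyx$truth$centers)  # same tray
  expect_gt(mean(stem$truth$true_fraction),
            mean(calyx$truth$true_fraction))
  # the two sides average back to the whole-fruit severity (the calyx-disc
  # exclusion shifts per-side fractions slightly, so the match is loose)
  expect_lt(abs(mean(two_side_ratio(stem$truth$true_fraction,
                                    calyx$truth$true_fraction)) -
                  mean(stem$truth$severity)), 0.06)
})

test_that("human assessment sees only the central slice", {
  cfg <- small_phantom()
  sc <- make_scene(cfg, "steel60", seed = 6)
  truth <- sc$truth

  # noise-free assessment equals the central-row bruise share
  a0 <- simulate_human_assessment(truth, noise_sd = 0, seed = 1)
  k <- 1
  cr <- truth$centers[k, 1]
  sel <- truth$labels[cr, ] == k
  expect_equal(a0[k], sum(truth$bruise_mask[cr, sel]) / sum(sel))

  # a bruise moved entirely off the slice row becomes invisible
  t2 <- truth
  onrow <- which(t2$labels[cr, ] == k)
  t2$bruise_mask[, ] <- 0L
  t2$bruise_mask[cr + 6, onrow] <- 1L  # off-slice bruise, same berry
  expect_equal(simulate_human_assessment(t2, noise_sd = 0, seed = 1)[k], 0)

  # a fully bruised berry is assessed at ~1
  full <- make_scene(cfg, "fully_bruised", seed = 6)
  af <- simulate_human_assessment(full$truth, noise_sd = 0, seed = 1)
  expect_gte(min(af), 0.9)

  # all values stay within [0, 1] under noise
  an <- simulate_human_assessment(truth, noise_sd = 0.3, seed = 2)
  expect_true(all(an >= 0 & an <= 1))
})

test_that("two datasets differing by illumination agree after normalization", {
  lib1 <- sample_pixel_spectra(phantom_config(dataset_scale = 1.0),
                               "healthy", 80, seed = 1)
  lib2 <- sample_pixel_spectra(phantom_config(dataset_scale = 1.15),
                               "healthy", 80, seed = 1)
  # before normalization the second dataset is brighter ...
  expect_gt(mean(lib2$spectra), 1.1 * mean(lib1$spectra))
  # ... and normalization removes the difference entirely
  n1 <- colMeans(normalize_spectra(lib1)$spectra)
  n2 <- colMeans(normalize_spectra(lib2)$spectra)
  expect_equal(n1, n2, tolerance = 1e-10)
})

test_that("scene too small for its berries is rejected", {
  expect_error(phantom_config(rows = 60, cols = 60, n_berries = 25),
               "overlap")
})
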