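test_that("separable classes train to perfect accuracy", {
  lib <- point_cloud_library(separation = 1, sigma = 0.05)
  model <- train_classifier(lib)
  cm <- evaluate(model, lib)
  expect_identical(cm$fn + cm$fp, 0L)
  expect_equal(confusion_stats(cm)$accuracy, 100)
})

test_that("indistinguishable classes cross-validate at chance", {
  lib <- point_cloud_library(separation = 0, sigma = 0.05,
                             n_per_class = 50)
  cv <- cross_validate(lib, k = 5, repeats = 2, seed = 3)
  expect_lt(abs(cv$mean_accuracy - 50), 12)
})

test_that("cross validation is deterministic under its seed", {
  lib <- point_cloud_library(separation = 0.3, sigma = 0.15,
                             n_per_class = 30)
  a <- cross_validate(lib, k = 5, repeats = 2, seed = 21)
  b <- cross_validate(lib, k = 5, repeats = 2, seed = 21)
  expect_identical(a$run_accuracies, b$run_accuracies)
})

test_that("training and evaluation guard their preconditions", {
  lib <- point_cloud_library()
  one_class <- lib
  keep <- lib$class_labels == "healthy"
  one_class$spectra <- lib$spectra[keep, ]
  one_class$class_labels <- lib$class_labels[keep]
  expect_error(train_classifier(one_class), "both classes")

  raw_lib <- lib
  raw_lib$normalized <- FALSE
  expect_error(train_classifier(raw_lib), "normalized")

  model <- train_classifier(lib)
  empty <- lib
  empty$spectra <- lib$spectra[0, , drop = FALSE]
  empty$class_labels <- lib$class_labels[0]
  expect_error(evaluate(model, empty), "empty")

  other_grid <- point_cloud_library(n_bands = 5)
  expect_error(evaluate(model, other_grid), "grid")

  expect_error(cross_validate(point_cloud_library(n_per_class = 5), k = 10),
               "fewer observations")
})

test_that("confusion statistics reproduce the published arithmetic", {
  s <- confusion_stats(list(tp = 42773, fn = 2193, fp = 1179, tn = 43787))
  expect_equal(s$tpr, 95.12)
  expect_equal(s$tnr, 97.38)
  expect_equal(s$fpr, 2.62)
  expect_equal(s$accuracy, 96.25)

  expect_equal(unlist(confusion_stats(list(tp = 1, fn = 0, fp = 0, tn = 1))),
               c(tpr = 100, tnr = 100, fpr = 0, fnr = 0, accuracy = 100))
  expect_equal(confusion_stats(list(tp = 0, fn = 1, fp = 1, tn = 0))$accuracy,
               0)
  expect_error(confusion_stats(list(tp = 0, fn = 0, fp = 1, tn = 1)),
               "both actual classes")
})

test_that("confusion rates respect their complements and bounds", {
  set.seed(8)
  for (i in 1:20) {
    cm <- as.list(rmultinom(1, 500, c(0.4, 0.1, 0.1, 0.4))[, 1] + 1L)
    names(cm) <- c("tp", "fn", "fp", "tn")
    s <- confusion_stats(cm)
    expect_true(all(unlist(s) >= 0 & unlist(s) <= 100))
    expect_equal(s$fpr, round(100 - s$tnr, 2))
    expect_equal(s$fnr, round(100 - s$tpr, 2))
  }
})

test_that("image classification respects background and exclusion", {
  cfg <- small_phantom()
  sc <- make_scene(cfg, "control", seed = 13)
  refl <- suppressWarnings(flat_field_correct(sc$raw, sc$white, sc$dark))
  mask <- refine_mask(threshold_mask(band_image(sc$raw, 1075), 942), 50)
  lm <- label_components(mask)
  excl <- calyx_exclusion_mask(lm, 5)

  lib <- merge_libraries(
    sample_pixel_spectra(cfg, "healthy", 250, seed = 1),
    sample_pixel_spectra(cfg, "bruised", 250, seed = 2))
  model <- train_classifier(normalize_spectra(lib))
  ci <- classify_image(model, refl, lm, excl)

  expect_true(all(ci$classes[lm$labels == 0L] == 0L))
  expect_true(all(ci$classes[excl == 1L] == 3L))
  expect_true(all(ci$classes[lm$labels > 0L & excl == 0L] %in% c(1L, 2L)))

  # a control scene is essentially all healthy tissue
  berry <- lm$labels > 0L & excl == 0L
  expect_lt(mean(ci$classes[berry] == 2L), 0.05)

  # exclusion covering a whole berry leaves no tissue pixels on it
  full_excl <- (lm$labels == 1L) * 1L
  ci2 <- classify_image(model, refl, lm, full_excl)
  expect_true(all(ci2$classes[lm$labels == 1L] == 3L))
})

test_that("CV accuracy does not improve with more sensor noise", {
  noise_levels <- c(0.01, 0.05, 0.12)
  acc <- sapply(noise_levels, function(ns) {
    mean(sapply(1:3, function(s) {
      cfg <- small_phantom(noise_sd = ns)
      lib <- normalize_spectra(merge_libraries(
        sample_pixel_spectra(cfg, "healthy", 120, seed = s),
        sample_pixel_spectra(cfg, "bruised", 120, seed = s + 100)))
      cross_validate(lib, k = 5, repeats = 1, seed = s)$mean_accuracy
    }))
  })
  expect_true(all(diff(acc) <= 0.5))  # non-increasing up to simulation noise
})
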