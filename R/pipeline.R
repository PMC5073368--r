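# End-to-end pipeline: phantom (or supplied) scenes -> flat-field
# calibration -> segmentation -> spectral library -> classifier -> pixel
# classification -> bruise ratio index -> statistics. Stage order follows
# the processing flowchart of the reference protocol; any stage failure
# aborts with the stage name.

#' Pipeline configuration
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param treatments Treatments quantified (training always uses control and
#'   fully_bruised scenes in phantom mode).
#' @param sides `c("stem", "calyx")` for two-side imaging or `"single"`.
#' @param threshold_dn Segmentation threshold on the raw DN scale.
#' @param segment_band_nm Band used for thresholding (default 1075 nm).
#' @param min_object_px Minimum component area kept by [refine_mask()].
#' @param calyx_radius_px Calyx exclusion disc radius.
#' @param norm_method Spectral normalization, `"mean"` or `"snv"`.
#' @param svm_cost,svm_gamma Classifier parameters (`NULL` gamma = 1/bands).
#' @param cv_folds,cv_repeats Cross-validation design.
#' @param bruise_threshold Bruised-call threshold on the index.
#' @param max_spectra_per_class Cap on training spectra per class (the
#'   extracted libraries are subsampled to this size after balancing).
#' @param phantom A [phantom_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            treatments = c("control", "steel60", "steel120",
                                           "pad120"),
                            sides = c("stem", "calyx"),
                            threshold_dn = 942,
                            segment_band_nm = 1075,
                            min_object_px = 50,
                            calyx_radius_px = 5,
                            norm_method = "mean",
                            svm_cost = 1,
                            svm_gamma = NULL,
                            cv_folds = 10,
                            cv_repeats = 3,
                            bruise_threshold = 0.2,
                            max_spectra_per_class = 600,
                            phantom = phantom_config(),
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# calibrate + segment one scene; returns reflectance cube, label map,
# exclusion mask
.process_scene <- function(scene, config) {
  refl <- .stage("calibrate",
                 suppressWarnings(flat_field_correct(scene$raw, scene$white,
                                                     scene$dark)))
  labmap <- .stage("segment", {
    dn_band <- band_image(scene$raw, config$segment_band_nm)
    mask <- threshold_mask(dn_band, config$threshold_dn)
    mask <- refine_mask(mask, config$min_object_px)
    label_components(mask)
  })
  excl <- .stage("calyx_exclusion",
                 calyx_exclusion_mask(labmap, config$calyx_radius_px))
  list(refl = refl, labmap = labmap, excl = excl)
}

# build the training library from phantom control and fully-bruised scenes,
# using the generator's truth masks in place of hand-drawn ROIs
.phantom_training_library <- function(config) {
  seed <- config$seed
  healthy_scene <- make_scene(config$phantom, "control",
                              derive_seed(seed, "train-healthy"))
  bruised_scene <- make_scene(config$phantom, "fully_bruised",
                              derive_seed(seed, "train-bruised"))
  ph <- .process_scene(healthy_scene, config)
  pb <- .process_scene(bruised_scene, config)
  roi_h <- (ph$labmap$labels > 0L & ph$excl == 0L) * 1L
  roi_b <- ((bruised_scene$truth$bruise_mask == 1L) &
              (pb$labmap$labels > 0L) & pb$excl == 0L) * 1L
  lib <- .stage("extract", {
    lh <- extract_roi_spectra(ph$refl, roi_h, "healthy", "phantom-control")
    lb <- extract_roi_spectra(pb$refl, roi_b, "bruised", "phantom-bruised")
    merge_libraries(lh, lb)
  })
  lib <- balance_library(lib, seed = derive_seed(seed, "balance"))
  # cap the library size for tractable training
  cap <- config$max_spectra_per_class
  per_class <- sum(lib$class_labels == "healthy")
  if (per_class > cap) {
    keep <- local_seed(derive_seed(seed, "subsample"), {
      c(sample(which(lib$class_labels == "healthy"), cap),
        sample(which(lib$class_labels == "bruised"), cap))
    })
    keep <- sort(keep)
    lib$spectra <- lib$spectra[keep, , drop = FALSE]
    lib$class_labels <- lib$class_labels[keep]
  }
  normalize_spectra(lib, method = config$norm_method)
}

#' Run the full phantom pipeline
#'
#' Generates scenes for the configured treatments, trains the pixel
#' classifier from phantom control and fully-bruised scenes, classifies
#' every scene with calyx exclusion, assembles the per-fruit bruise report
#' (two-side index, firmness, simulated human assessment), and runs the
#' statistical comparisons. Deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return List: `report` (per-fruit data.frame), `cv` (cross-validation of
#'   the training library), `stats` (Kruskal-Wallis letters across
#'   treatments and the index-vs-human regression), `model`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  lib <- .stage("library", .phantom_training_library(config))
  model <- .stage("train",
                  train_classifier(lib, cost = config$svm_cost,
                                   gamma = config$svm_gamma,
                                   seed = derive_seed(seed, "train")))
  cv <- .stage("cv", cross_validate(lib, k = config$cv_folds,
                                    repeats = config$cv_repeats,
                                    seed = derive_seed(seed, "cv"),
                                    cost = config$svm_cost,
                                    gamma = config$svm_gamma))

  rows <- list()
  for (trt in config$treatments) {
    per_side <- list()
    side_truth <- list()
    truth0 <- NULL
    for (sd_ in config$sides) {
      scene <- make_scene(config$phantom, trt,
                          derive_seed(seed, paste0("scene-", trt)),
                          side = sd_)
      if (is.null(truth0)) truth0 <- scene$truth
      side_truth[[sd_]] <- scene$truth$true_fraction
      ps <- .process_scene(scene, config)
      ci <- .stage("classify", classify_image(model, ps$refl, ps$labmap,
                                              ps$excl))
      # report ratios in the tray's fruit order (centers match across sides)
      m <- match_berries(scene$truth$centers, ps$labmap$centers)
      per_side[[sd_]] <- bruise_ratios(ci)[m]
    }
    if (length(per_side) == 2L) {
      ratio <- .stage("quantify", two_side_ratio(per_side[[1]],
                                                 per_side[[2]]))
      true_frac <- two_side_ratio(side_truth[[1]], side_truth[[2]])
    } else {
      ratio <- per_side[[1]]
      true_frac <- side_truth[[1]]
    }
    human <- simulate_human_assessment(
      truth0, seed = derive_seed(seed, paste0("human-", trt)))
    rows[[trt]] <- data.frame(
      treatment = trt,
      berry_id = seq_along(ratio),
      bruise_ratio = ratio,
      bruised = call_bruised(ratio, config$bruise_threshold),
      true_fraction = true_frac,
      severity = truth0$severity,
      firmness = truth0$firmness,
      human_assessment = human
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  stats_out <- .stage("compare", {
    by_trt <- split(report$bruise_ratio, report$treatment)
    res <- list(kw = kw_multcomp(by_trt, alpha = 0.05))
    if (stats::var(report$human_assessment) > 0) {
      res$linreg <- linreg_index_vs_human(report$human_assessment,
                                          report$bruise_ratio)
    }
    res
  })

  out <- list(report = report, cv = cv, stats = stats_out, model = model,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
    manifest <- list(
      seed = seed,
      treatments = config$treatments,
      sides = config$sides,
      threshold_dn = config$threshold_dn,
      bruise_threshold = config$bruise_threshold,
      cv_accuracy = cv$mean_accuracy,
      letters = as.list(stats_out$kw$letters),
      r_squared = if (!is.null(stats_out$linreg))
        stats_out$linreg$r_squared else NA
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
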