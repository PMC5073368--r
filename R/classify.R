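# Pixel-spectrum classification: soft-margin RBF support-vector classifier
# (libsvm via e1071) with the library defaults the reference protocol used
# (cost 1, kernel width 1/#bands, no tuning), stratified k-fold cross
# validation, confusion statistics, and whole-image classification with
# calyx exclusion.

#' Train the healthy/bruised pixel classifier
#'
#' Fits a soft-margin support-vector classifier with a radial-basis kernel
#' on a balanced, normalized spectral library. Defaults are libsvm's: cost
#' 1, kernel width `1/B` for `B` bands; no rescaling is applied (the spectra
#' are already normalized).
#'
#' @param lib Balanced, normalized `spectral_library`.
#' @param cost Soft-margin cost parameter.
#' @param gamma Radial-basis kernel width; default `1/ncol(spectra)`.
#' @param seed Seed recorded in the model metadata (libsvm training itself
#'   is deterministic for fixed input).
#' @return A `bruise_classifier`: the fitted SVM plus training metadata
#'   (band grid, normalization method, parameters, library fingerprint).
#' @export
train_classifier <- function(lib, cost = 1, gamma = NULL, seed = 17) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!lib$normalized) stop("train on a normalized library (see normalize_spectra)")
  if (nlevels(droplevels(lib$class_labels)) < 2L) {
    stop("training library must contain both classes")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(lib$spectra)
  fit <- local_seed(seed, e1071::svm(
    x = lib$spectra, y = lib$class_labels,
    kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
  ))
  structure(
    list(svm = fit,
         wavelengths = lib$wavelengths,
         norm_method = if (is.null(lib$norm_method)) "mean" else lib$norm_method,
         params = list(cost = cost, gamma = gamma, kernel = "radial"),
         seed = seed,
         n_train = nrow(lib$spectra),
         library_hash = sum(lib$spectra) + nrow(lib$spectra)),
    class = "bruise_classifier"
  )
}

#' @export
print.bruise_classifier <- function(x, ...) {
  cat(sprintf(
    "<bruise_classifier> RBF SVM, cost=%g gamma=%.4g, trained on %d spectra (%d SVs)\n",
    x$params$cost, x$params$gamma, x$n_train, x$svm$tot.nSV))
  invisible(x)
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("fewer observations than folds in class ", cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross validation of the pixel classifier
#'
#' Accuracy is averaged over folds within a run; the reported spread is the
#' standard deviation across `repeats` runs with re-randomized fold
#' assignments.
#'
#' @param lib Balanced, normalized `spectral_library`.
#' @param k Number of folds (default 10).
#' @param repeats Number of re-randomized CV runs (default 5).
#' @param seed RNG seed for fold assignment.
#' @param cost,gamma Classifier parameters, as in [train_classifier()].
#' @return List with `mean_accuracy` and `sd_accuracy` (percent), and the
#'   per-run accuracies.
#' @export
cross_validate <- function(lib, k = 10, repeats = 5, seed = 17,
                           cost = 1, gamma = NULL) {
  stopifnot(inherits(lib, "spectral_library"), k >= 2)
  if (is.null(gamma)) gamma <- 1 / ncol(lib$spectra)
  y <- droplevels(lib$class_labels)
  if (nlevels(y) < 2L) stop("cross validation needs both classes")
  run_acc <- local_seed(seed, vapply(seq_len(repeats), function(r) {
    fold <- .stratified_folds(lib$class_labels, k)
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- e1071::svm(x = lib$spectra[tr, , drop = FALSE],
                        y = lib$class_labels[tr],
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      pred <- stats::predict(fit, lib$spectra[!tr, , drop = FALSE])
      mean(pred == lib$class_labels[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1)))
  list(mean_accuracy = 100 * mean(run_acc),
       sd_accuracy = if (repeats > 1) 100 * stats::sd(run_acc) else NA_real_,
       run_accuracies = 100 * run_acc,
       k = k, repeats = repeats, seed = seed)
}

#' Evaluate a classifier on an independent test library
#'
#' @param model A `bruise_classifier`.
#' @param test_lib Normalized `spectral_library` (same band grid and
#'   normalization method as the training library).
#' @return A `confusion_matrix`: counts `tp`, `fn`, `fp`, `tn` with bruised
#'   as the positive class.
#' @export
evaluate <- function(model, test_lib) {
  stopifnot(inherits(model, "bruise_classifier"),
            inherits(test_lib, "spectral_library"))
  if (nrow(test_lib$spectra) == 0L) stop("test library is empty")
  if (!isTRUE(all.equal(model$wavelengths, test_lib$wavelengths))) {
    stop("test library is on a different wavelength grid")
  }
  if (!test_lib$normalized) stop("test library must be normalized")
  tl_method <- if (is.null(test_lib$norm_method)) "mean" else test_lib$norm_method
  if (!identical(tl_method, model$norm_method)) {
    stop("test library normalization does not match the model")
  }
  pred <- stats::predict(model$svm, test_lib$spectra)
  truth <- test_lib$class_labels
  cm <- list(
    tp = sum(pred == "bruised" & truth == "bruised"),
    fn = sum(pred == "healthy" & truth == "bruised"),
    fp = sum(pred == "bruised" & truth == "healthy"),
    tn = sum(pred == "healthy" & truth == "healthy")
  )
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Rates and accuracy from a confusion matrix
#'
#' Percentages are reported to two decimals, with bruised as the positive
#' class: sensitivity (true positive rate), specificity (true negative
#' rate), their complements, and overall accuracy.
#'
#' @param cm A `confusion_matrix` or a list/vector with `tp`, `fn`, `fp`,
#'   `tn`.
#' @return Named list: `tpr`, `tnr`, `fpr`, `fnr`, `accuracy`, in percent.
#' @examples
#' confusion_stats(list(tp = 42773, fn = 2193, fp = 1179, tn = 43787))
#' @export
confusion_stats <- function(cm) {
  cm <- as.list(cm)
  stopifnot(all(c("tp", "fn", "fp", "tn") %in% names(cm)))
  with(cm, {
    if (tp + fn == 0 || fp + tn == 0) {
      stop("confusion matrix needs observations in both actual classes")
    }
    tpr <- 100 * tp / (tp + fn)
    tnr <- 100 * tn / (fp + tn)
    list(tpr = round(tpr, 2), tnr = round(tnr, 2),
         fpr = round(100 - tnr, 2), fnr = round(100 - tpr, 2),
         accuracy = round(100 * (tp + tn) / (tp + fn + fp + tn), 2))
  })
}

#' Classify a segmented hyperspectral image at the pixel level
#'
#' Every berry pixel outside the calyx-exclusion disc is classified from its
#' normalized spectrum; background keeps the label-map zeros and excluded
#' pixels are never assigned a tissue class.
#'
#' @param model A `bruise_classifier`.
#' @param cube Reflectance `hypercube`.
#' @param labelmap `label_map` from [label_components()].
#' @param exclusion_mask 0/1 matrix from [calyx_exclusion_mask()], or `NULL`
#'   for no exclusion.
#' @return A `classified_image`: integer matrix `classes` coded 0 =
#'   background, 1 = healthy, 2 = bruised, 3 = excluded, plus the source
#'   `label_map`.
#' @export
classify_image <- function(model, cube, labelmap, exclusion_mask = NULL) {
  stopifnot(inherits(model, "bruise_classifier"),
            inherits(cube, "hypercube"), inherits(labelmap, "label_map"))
  if (cube$kind != "reflectance") stop("classify a calibrated cube")
  d <- dim(cube$data)
  if (!identical(dim(labelmap$labels), d[1:2])) {
    stop("label map does not match the cube dimensions")
  }
  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(0L, d[1], d[2])
  } else if (!identical(dim(exclusion_mask), d[1:2])) {
    stop("exclusion mask does not match the cube dimensions")
  }
  classes <- matrix(0L, d[1], d[2])
  excl <- exclusion_mask != 0 & labelmap$labels > 0L
  classes[excl] <- 3L
  idx <- which(labelmap$labels > 0L & !excl)
  if (length(idx) > 0L) {
    flat <- matrix(cube$data, d[1] * d[2], d[3])
    spectra <- normalize_spectra(flat[idx, , drop = FALSE],
                                 method = model$norm_method)
    pred <- stats::predict(model$svm, spectra)
    classes[idx] <- ifelse(pred == "bruised", 2L, 1L)
  }
  structure(list(classes = classes, labelmap = labelmap,
                 coding = c(background = 0L, healthy = 1L, bruised = 2L,
                            excluded = 3L)),
            class = "classified_image")
}

#' @export
print.classified_image <- function(x, ...) {
  tab <- tabulate(x$classes + 1L, nbins = 4L)
  cat(sprintf(
    "<classified_image> %d x %d: %d background, %d healthy, %d bruised, %d excluded\n",
    nrow(x$classes), ncol(x$classes), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}
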