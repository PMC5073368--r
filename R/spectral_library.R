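# Labeled pixel-spectrum libraries: extraction from ROIs, normalization,
# class balancing, and merging.

.new_spectral_library <- function(spectra, class_labels, wavelengths,
                                  source_tag = "", normalized = FALSE) {
  stopifnot(is.matrix(spectra), nrow(spectra) == length(class_labels),
            ncol(spectra) == length(wavelengths))
  if (any(!is.finite(spectra))) stop("library spectra must be finite")
  structure(
    list(spectra = spectra,
         class_labels = factor(class_labels, levels = c("healthy", "bruised")),
         wavelengths = wavelengths,
         source_tag = source_tag,
         normalized = normalized),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  tab <- table(x$class_labels)
  cat(sprintf(
    "<spectral_library> %d spectra x %d bands (%s)%s  healthy=%d bruised=%d\n",
    nrow(x$spectra), ncol(x$spectra),
    if (x$normalized) "normalized" else "reflectance",
    if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else "",
    tab[["healthy"]], tab[["bruised"]]))
  invisible(x)
}

#' Extract pixel spectra from a region of interest
#'
#' Pulls one spectrum per foreground mask pixel out of a calibrated cube and
#' tags every row with a tissue class. Rows follow raster-scan (row-major)
#' order of the mask.
#'
#' @param cube Reflectance `hypercube`.
#' @param roi_mask 0/1 matrix matching the cube's spatial dimensions.
#' @param class_label `"healthy"` or `"bruised"`.
#' @param source_tag Free-text provenance recorded in the library.
#' @return A `spectral_library`.
#' @export
extract_roi_spectra <- function(cube, roi_mask, class_label,
                                source_tag = "") {
  stopifnot(inherits(cube, "hypercube"), is.matrix(roi_mask))
  if (cube$kind != "reflectance") {
    stop("extract_roi_spectra expects a calibrated (reflectance) cube")
  }
  class_label <- match.arg(class_label, c("healthy", "bruised"))
  d <- dim(cube$data)
  if (!identical(dim(roi_mask), d[1:2])) {
    stop("ROI mask dimensions do not match the cube")
  }
  idx <- which(roi_mask != 0)
  if (length(idx) == 0L) stop("ROI mask is empty")
  rr <- (idx - 1L) %% d[1] + 1L
  cc <- (idx - 1L) %/% d[1] + 1L
  ord <- order(rr, cc)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  spectra <- flat[idx[ord], , drop = FALSE]
  .new_spectral_library(spectra, rep(class_label, length(idx)),
                        cube$grid$values, source_tag = source_tag)
}

#' Normalize spectra against multiplicative illumination differences
#'
#' Default method divides each spectrum by its own mean over bands, so the
#' result has mean 1 and is invariant to a positive scale factor --- the
#' between-instrument intensity difference this removes is multiplicative.
#' `"snv"` (standard normal variate: per-spectrum centering and unit-variance
#' scaling) is available as an alternative.
#'
#' @param x A `spectral_library`, a spectra matrix, or a single spectrum.
#' @param method `"mean"` (default) or `"snv"`.
#' @return Same shape as the input; libraries are returned with
#'   `normalized = TRUE`.
#' @export
normalize_spectra <- function(x, method = c("mean", "snv")) {
  method <- match.arg(method)
  norm_mat <- function(m) {
    if (method == "mean") {
      mu <- rowMeans(m)
      if (any(mu <= 0)) stop("cannot mean-normalize a spectrum with mean <= 0")
      m / mu
    } else {
      mu <- rowMeans(m)
      s <- apply(m, 1, stats::sd)
      if (any(s == 0)) stop("cannot SNV-normalize a constant spectrum")
      (m - mu) / s
    }
  }
  if (inherits(x, "spectral_library")) {
    out <- x
    out$spectra <- norm_mat(x$spectra)
    out$normalized <- TRUE
    out$norm_method <- method
    return(out)
  }
  if (is.matrix(x)) return(norm_mat(x))
  as.vector(norm_mat(matrix(x, 1)))
}

#' Balance a spectral library by subsampling the majority class
#'
#' The minority class is kept whole; the majority class is subsampled
#' uniformly without replacement under the given seed, so both classes end
#' up with the minority count.
#'
#' @param lib A `spectral_library` containing both classes.
#' @param seed Integer RNG seed (default 17) controlling the subsample.
#' @return A balanced `spectral_library`.
#' @export
balance_library <- function(lib, seed = 17) {
  stopifnot(inherits(lib, "spectral_library"))
  tab <- table(lib$class_labels)
  if (any(tab == 0)) stop("both classes must be present to balance")
  if (tab[["healthy"]] == tab[["bruised"]]) return(lib)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  keep_min <- which(lib$class_labels == minority)
  maj_idx <- which(lib$class_labels == majority)
  keep_maj <- local_seed(seed, sample(maj_idx, min(tab)))
  sel <- sort(c(keep_min, keep_maj))
  .new_spectral_library(lib$spectra[sel, , drop = FALSE],
                        as.character(lib$class_labels[sel]),
                        lib$wavelengths, source_tag = lib$source_tag,
                        normalized = lib$normalized)
}

#' Merge two spectral libraries
#'
#' Row-wise concatenation preserving labels; inputs must share the band grid
#' and normalization state. Merging two balanced libraries yields a balanced
#' library with per-class count (N_a + N_b) / 2.
#'
#' @param a,b `spectral_library` objects.
#' @return The combined `spectral_library`.
#' @export
merge_libraries <- function(a, b) {
  stopifnot(inherits(a, "spectral_library"), inherits(b, "spectral_library"))
  if (nrow(b$spectra) == 0L) return(a)
  if (nrow(a$spectra) == 0L) return(b)
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stop("libraries are on different wavelength grids")
  }
  if (!identical(a$normalized, b$normalized)) {
    stop("libraries differ in normalization state")
  }
  .new_spectral_library(
    rbind(a$spectra, b$spectra),
    c(as.character(a$class_labels), as.character(b$class_labels)),
    a$wavelengths,
    source_tag = paste(c(a$source_tag, b$source_tag)[
      nzchar(c(a$source_tag, b$source_tag))], collapse = "+"),
    normalized = a$normalized
  )
}

#' Write / read a spectral library as CSV
#'
#' One row per spectrum: `class`, `source`, then one reflectance column per
#' band, headed by the wavelength in nm.
#'
#' @param lib A `spectral_library`.
#' @param path CSV path.
#' @return `write_library_csv` returns `path` invisibly; `read_library_csv`
#'   returns a `spectral_library`.
#' @export
write_library_csv <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  df <- data.frame(class = as.character(lib$class_labels),
                   source = lib$source_tag,
                   lib$spectra, check.names = FALSE)
  names(df)[-(1:2)] <- format(lib$wavelengths, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @param normalized Whether the stored spectra are normalized.
#' @export
read_library_csv <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(df)[-(1:2)])
  .new_spectral_library(as.matrix(df[, -(1:2), drop = FALSE]),
                        df$class, wl,
                        source_tag = if (nrow(df)) df$source[1] else "",
                        normalized = normalized)
}
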