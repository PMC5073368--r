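# Berry segmentation: morphological mask refinement, connected-component
# labeling (8-connectivity by default), and calyx-end exclusion discs.

.label4 <- function(mask) {
  # EBImage::bwlabel labels 4-connected components
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

.merge_diagonal <- function(lab) {
  # upgrade 4-connected labels to 8-connectivity: union-find over label
  # pairs that touch diagonally
  n_lab <- max(lab)
  if (n_lab < 2L) return(lab)
  parent <- seq_len(n_lab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  # compact to 1..N preserving first-appearance order
  remap <- integer(n_lab)
  remap[sort(unique(root))] <- seq_along(unique(sort(root)))
  out <- lab
  out[out > 0L] <- remap[root[lab[lab > 0L]]]
  out
}

#' Refine a binary segmentation mask
#'
#' Fills interior holes and removes connected foreground specks smaller
#' than `min_object_px`, the standard cleanup between thresholding and
#' component labeling.
#'
#' @param mask Integer/logical 0/1 matrix.
#' @param min_object_px Minimum component area kept, in pixels.
#' @param connectivity 8 (default) or 4, used for the speck removal.
#' @return Integer 0/1 matrix.
#' @export
refine_mask <- function(mask, min_object_px = 50, connectivity = 8) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1L
  filled <- EBImage::fillHull(m)
  filled <- matrix(as.integer(EBImage::imageData(filled) != 0),
                   nrow(m), ncol(m))
  lab <- .label4(filled)
  if (connectivity == 8) lab <- .merge_diagonal(lab)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_object_px)
    filled <- (lab %in% keep & lab > 0L) * 1L
    dim(filled) <- dim(m)
  }
  storage.mode(filled) <- "integer"
  filled
}

#' Label connected components of a berry mask
#'
#' Each connected foreground component becomes one berry. Berries are
#' numbered in raster-scan order of their first pixel; the component center
#' is the pixel centroid rounded to the nearest pixel.
#'
#' @param mask Refined binary mask.
#' @param connectivity 8 (default) or 4.
#' @return A `label_map`: list with `labels` (integer matrix, 0 background)
#'   and `centers` (N x 2 matrix of row/col centers).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- (mask != 0) * 1L
  lab <- .label4(m)
  if (connectivity == 8) lab <- .merge_diagonal(lab)
  n <- max(lab)
  if (n == 0L) {
    warning("no connected components found")
    centers <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("row", "col")))
    return(structure(list(labels = lab, centers = centers),
                     class = "label_map"))
  }
  # renumber by raster-scan (row-major) order of each component's first pixel
  idx <- which(lab > 0L)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  scan_pos <- (rr - 1L) * ncol(lab) + cc
  first_seen <- vapply(seq_len(n), function(k) min(scan_pos[lab[idx] == k]),
                       numeric(1))
  order_map <- integer(n)
  order_map[order(first_seen)] <- seq_len(n)
  lab[idx] <- order_map[lab[idx]]

  centers <- t(vapply(seq_len(n), function(k) {
    sel <- lab[idx] == k
    c(round(mean(rr[sel])), round(mean(cc[sel])))
  }, numeric(2)))
  colnames(centers) <- c("row", "col")
  structure(list(labels = lab, centers = centers), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d berries on a %d x %d raster\n",
              nrow(x$centers), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Calyx-end exclusion mask
#'
#' The calyx end reflects little NIR light and mimics bruised tissue, so a
#' fixed-radius disc at each berry's component center is excluded from
#' classification. Membership is the closed disc (squared pixel distance to
#' the center at most radius squared), clipped to that berry's own pixels.
#'
#' @param labelmap A `label_map`.
#' @param radius_px Disc radius in pixels (default 5).
#' @return Integer 0/1 matrix; 1 marks excluded pixels.
#' @export
calyx_exclusion_mask <- function(labelmap, radius_px = 5) {
  stopifnot(inherits(labelmap, "label_map"), radius_px >= 0)
  lab <- labelmap$labels
  excl <- matrix(0L, nrow(lab), ncol(lab))
  n <- nrow(labelmap$centers)
  if (n == 0L) return(excl)
  r2 <- radius_px^2
  for (k in seq_len(n)) {
    cr <- labelmap$centers[k, 1]; cc <- labelmap$centers[k, 2]
    rows <- max(1, cr - radius_px):min(nrow(lab), cr + radius_px)
    cols <- max(1, cc - radius_px):min(ncol(lab), cc + radius_px)
    sub <- outer((rows - cr)^2, (cols - cc)^2, `+`) <= r2
    sub <- sub & (lab[rows, cols, drop = FALSE] == k)
    excl[rows, cols][sub] <- 1L
  }
  excl
}
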