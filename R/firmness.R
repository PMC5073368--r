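# Reference firmness and chemometric firmness prediction.
#
# Firmness is the least-squares slope (N/mm) of a parallel-plate
# force/deformation curve restricted to the 0.5-2.5 mm window, where the
# curve is close to straight. Prediction from mean berry spectra uses
# partial least squares regression fitted by NIPALS: components maximize
# predictor-response covariance and the predictor block is deflated after
# each extraction, so the fit is deterministic for fixed input.

#' Firmness from a force/deformation curve
#'
#' @param deformation Deformation samples in mm, strictly increasing.
#' @param force Force samples in N, same length.
#' @param window Fitting window in mm (default `c(0.5, 2.5)`).
#' @return Least-squares slope in N/mm over the window.
#' @export
firmness_slope <- function(deformation, force, window = c(0.5, 2.5)) {
  stopifnot(length(deformation) == length(force),
            !is.unsorted(deformation, strictly = TRUE))
  inw <- deformation >= window[1] & deformation <= window[2]
  if (sum(inw) < 2L) stop("need at least 2 samples inside the fitting window")
  unname(stats::coef(stats::lm(force[inw] ~ deformation[inw]))[2])
}

#' Mean spectrum of one berry
#'
#' Per-band mean reflectance over all of the berry's pixels. The calyx
#' exclusion applies only to classification, not to firmness prediction, so
#' no pixels are dropped here.
#'
#' @param cube Reflectance `hypercube`.
#' @param labelmap A `label_map`.
#' @param berry_id Positive berry label.
#' @return Numeric spectrum of length `bands`.
#' @export
mean_spectrum <- function(cube, labelmap, berry_id) {
  stopifnot(inherits(cube, "hypercube"), inherits(labelmap, "label_map"))
  d <- dim(cube$data)
  idx <- which(labelmap$labels == berry_id)
  if (length(idx) == 0L) stop("berry ", berry_id, " not present")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Mean spectra of every berry in a scene
#'
#' @inheritParams mean_spectrum
#' @return Matrix, one row per berry.
#' @export
mean_spectra <- function(cube, labelmap) {
  n <- nrow(labelmap$centers)
  t(vapply(seq_len(n), mean_spectrum, numeric(dim(cube$data)[3]),
           cube = cube, labelmap = labelmap))
}

.nipals_pls <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  if (ncomp == 0L) stop("response is orthogonal to the predictors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = as.vector(beta), ncomp = ncomp)
}

#' Fit a partial least squares regression of firmness on spectra
#'
#' NIPALS PLSR on column-centered predictors and a centered response. With
#' `n_components = NULL`, the component count is chosen by 10-fold cross
#' validation minimizing RMSEP, capped at `max_components`.
#'
#' @param X Predictor matrix (one mean spectrum per row).
#' @param y Response vector (firmness, N/mm).
#' @param n_components Number of latent components, or `NULL` to select by CV.
#' @param max_components Cap for CV selection (default 20).
#' @param cv_folds Folds used when selecting the component count.
#' @param seed RNG seed for the CV fold split.
#' @return A `plsr_model`: centering vectors, regression vector, component
#'   count, and training RMSE.
#' @export
plsr_fit <- function(X, y, n_components = NULL, max_components = 20,
                     cv_folds = 10, seed = 17) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("response is constant")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  rank_cap <- qr(Xc)$rank
  if (!is.null(n_components)) {
    if (n_components > rank_cap) {
      stop(sprintf("n_components (%d) exceeds predictor rank (%d)",
                   n_components, rank_cap))
    }
    if (nrow(X) < n_components + 1) stop("need more rows than components")
    ncomp <- n_components
  } else {
    cap <- min(max_components, rank_cap, nrow(X) - 2L)
    folds <- local_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
    press <- numeric(cap)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      cum <- .pls_path_predict(X[tr, , drop = FALSE], y[tr],
                               X[!tr, , drop = FALSE], cap)
      for (a in seq_len(cap)) {
        press[a] <- press[a] + sum((cum[, a] - y[!tr])^2)
      }
    }
    ncomp <- which.min(press)
  }
  pls <- .nipals_pls(Xc, yc, ncomp)
  fitted <- as.vector(Xc %*% pls$beta) + y_mean
  structure(
    list(n_components = pls$ncomp, x_mean = x_mean, y_mean = y_mean,
         coefficients = pls$beta,
         training_rmse = sqrt(mean((fitted - y)^2))),
    class = "plsr_model"
  )
}

# predictions of the PLS path (1..ncomp components) for new raw data
.pls_path_predict <- function(Xtr, ytr, Xnew, ncomp) {
  xm <- colMeans(Xtr); ym <- mean(ytr)
  Xd <- sweep(Xtr, 2, xm); yd <- ytr - ym
  Xt <- sweep(Xnew, 2, xm)
  n <- nrow(Xnew)
  out <- matrix(ym, n, ncomp)
  W <- matrix(0, ncol(Xtr), 0); P <- W; q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { if (a > 1) out[, a:ncomp] <- out[, a - 1]; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) { if (a > 1) out[, a:ncomp] <- out[, a - 1]; break }
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(p_); yd <- yd - q_ * t_
    W <- cbind(W, w); P <- cbind(P, p_); q <- c(q, q_)
    beta <- W %*% solve(crossprod(P, W), q)
    out[, a] <- as.vector(Xt %*% beta) + ym
  }
  out
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, training RMSE %.4g N/mm\n",
              x$n_components, x$training_rmse))
  invisible(x)
}

#' Predict firmness from spectra with a fitted PLSR model
#'
#' @param model A `plsr_model`.
#' @param X Spectra matrix on the training band grid.
#' @return Predicted firmness vector (N/mm).
#' @export
plsr_predict <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("prediction spectra are on a different band grid")
  }
  as.vector(sweep(X, 2, model$x_mean) %*% model$coefficients) + model$y_mean
}

#' Root mean squared error of prediction
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmsep <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ")
  }
  sqrt(mean((predicted - observed)^2))
}
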