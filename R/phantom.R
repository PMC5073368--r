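# Synthetic hyperspectral phantom generator.
#
# Emulates NIR (950-1650 nm) reflectance scenes of trays of blueberries on a
# dark background with known ground truth: healthy and bruised tissue
# spectra with water-absorption dips near 980/1200/1470 nm (only healthy
# tissue turns upward again past 1470 nm), a dark calyx spot at each berry
# center, smooth multiplicative illumination non-uniformity, white/dark
# reference cubes consistent with that illumination field, additive sensor
# noise, and per-berry firmness and simulated human assessment correlated
# with the true bruise fraction. Every scene is deterministic under its
# seed.

#' Phantom configuration
#'
#' @param rows,cols Scene size in pixels.
#' @param n_berries Berries per scene (default 25, one treatment replicate).
#' @param radius_range Berry radius range in pixels.
#' @param noise_sd Additive sensor noise, expressed on the reflectance scale
#'   (the DN noise injected is `noise_sd * (white - dark)`).
#' @param illum_amplitude Amplitude of the smooth multiplicative
#'   illumination gradient.
#' @param dataset_scale Global illumination scale; two "datasets" that
#'   differ only in this scale emulate two acquisitions whose spectra agree
#'   after normalization.
#' @param dn_max Digital-number ceiling (12-bit scale).
#' @param dark_level Dark-reference DN level.
#' @param calyx_radius_px Radius of the dark calyx spot.
#' @param mix_bruised_mean,mix_bruised_sd,mix_healthy_mean,mix_healthy_sd
#'   Parameters of the per-pixel healthy/bruised mixture weight inside and
#'   outside the bruise region. These set the class separation; the defaults
#'   are calibrated so 10-fold CV accuracy of the pixel classifier lands in
#'   the mid-90s at the default `noise_sd`.
#' @param firmness_intercept,firmness_slope,firmness_noise_sd Per-fruit
#'   firmness model: `firmness = intercept - slope * fraction + noise`
#'   (N/mm).
#' @param calyx_side_attenuation Bruise-severity multiplier on the calyx
#'   side (bruises are consistently more severe on the stem side).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(rows = 240, cols = 240, n_berries = 25,
                           radius_range = c(16, 20),
                           noise_sd = 0.02,
                           illum_amplitude = 0.12,
                           dataset_scale = 1.0,
                           dn_max = 4095,
                           dark_level = 120,
                           calyx_radius_px = 5,
                           mix_bruised_mean = 0.74,
                           mix_bruised_sd = 0.23,
                           mix_healthy_mean = 0.04,
                           mix_healthy_sd = 0.14,
                           firmness_intercept = 2.4,
                           firmness_slope = 1.5,
                           firmness_noise_sd = 0.075,
                           calyx_side_attenuation = 0.6) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_sd >= 0, cfg$n_berries >= 1,
            cfg$radius_range[1] <= cfg$radius_range[2])
  cell <- floor(min(rows, cols) / ceiling(sqrt(n_berries)))
  if (cell < 2 * radius_range[2] + 2) {
    stop("scene too small to place berries without overlap")
  }
  structure(cfg, class = "phantom_config")
}

# per-treatment mean true bruise fraction (drop-height/surface design)
.treatment_fractions <- c(control = 0, fully_bruised = 0.95,
                          steel60 = 0.30, steel120 = 0.50, pad120 = 0.15)

#' Reference healthy-tissue reflectance spectrum
#'
#' Smooth baseline minus Gaussian water-absorption dips at 980, 1200 and
#' 1470 nm; reflectance turns upward again between 1470 and 1650 nm.
#'
#' @param grid A `wavelength_grid`.
#' @return Reflectance spectrum (one value per band).
#' @export
healthy_spectrum <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  wl <- grid$values
  dip <- function(center, sd) exp(-0.5 * ((wl - center) / sd)^2)
  0.70 - 2e-4 * (wl - 950) -
    0.05 * dip(980, 20) - 0.12 * dip(1200, 40) - 0.38 * dip(1470, 55) +
    0.06 * pmax(0, wl - 1470) / 180
}

#' Reference bruised-tissue reflectance spectrum
#'
#' Lower overall reflectance, deeper water dips (more free water), and no
#' post-1470 nm upturn: the spectrum stays flat between 1470 and 1650 nm.
#'
#' @inheritParams healthy_spectrum
#' @return Reflectance spectrum, everywhere at or below the healthy one.
#' @export
bruised_spectrum <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  wl <- grid$values
  dip <- function(center, sd) exp(-0.5 * ((wl - center) / sd)^2)
  # the 1470 nm dip plateaus on its long-wavelength side: no upturn
  dip1470 <- ifelse(wl < 1470, dip(1470, 55), 1)
  0.50 - 0.08 * dip(980, 20) - 0.16 * dip(1200, 40) - 0.34 * dip1470
}

.clipnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# berry geometry on a jittered grid; deterministic under the active RNG
.place_berries <- function(cfg) {
  side <- ceiling(sqrt(cfg$n_berries))
  cell_r <- floor(cfg$rows / side)
  cell_c <- floor(cfg$cols / side)
  radii <- round(stats::runif(cfg$n_berries, cfg$radius_range[1],
                              cfg$radius_range[2]))
  centers <- matrix(0, cfg$n_berries, 2,
                    dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (k >= cfg$n_berries) break
      k <- k + 1L
      slack_r <- floor(cell_r / 2) - radii[k] - 1
      slack_c <- floor(cell_c / 2) - radii[k] - 1
      if (slack_r < 0 || slack_c < 0) {
        stop("berries cannot be placed without overlap")
      }
      centers[k, ] <- c(
        (i - 1) * cell_r + floor(cell_r / 2) +
          sample(seq(-slack_r, slack_r), 1),
        (j - 1) * cell_c + floor(cell_c / 2) +
          sample(seq(-slack_c, slack_c), 1)
      )
    }
  }
  list(centers = centers, radii = radii)
}

#' Generate one phantom scene with ground truth
#'
#' Builds a raw DN cube plus matching white and dark reference cubes for one
#' tray of berries under a treatment, together with the ground truth needed
#' to score every downstream stage.
#'
#' Per-fruit bruise severity is drawn from the treatment (seed-stable across
#' sides, so the stem and calyx images of the same tray share fruit
#' identity); the bruise is a one-sided cap of the berry disc covering the
#' target pixel fraction, biased in severity toward the stem side. Pixel
#' spectra are convex mixtures of the healthy and bruised reference spectra
#' with per-pixel mixture jitter, a multiplicative per-pixel scale, and
#' additive sensor noise.
#'
#' @param cfg A `phantom_config`.
#' @param treatment One of `"control"`, `"fully_bruised"`, `"steel60"`,
#'   `"steel120"`, `"pad120"`, or a number in `[0, 1]` taken as the mean
#'   true bruise fraction.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param side `"single"`, `"stem"` or `"calyx"`.
#' @param grid Wavelength grid (default 950-1650 nm, 5 nm).
#' @return List with `raw`, `white`, `dark` (`hypercube`s) and `truth`: true
#'   label matrix, bruise mask, centers, radii, per-berry true bruise
#'   fraction (calyx-disc excluded), whole-fruit severity, and firmness.
#' @export
make_scene <- function(cfg, treatment = "control", seed = 1,
                       side = c("single", "stem", "calyx"),
                       grid = make_wavelength_grid(950, 1650, 5)) {
  stopifnot(inherits(cfg, "phantom_config"))
  side <- match.arg(side)
  if (is.numeric(treatment)) {
    stopifnot(treatment >= 0, treatment <= 1)
    mu_frac <- treatment
  } else {
    treatment <- match.arg(treatment, names(.treatment_fractions))
    mu_frac <- .treatment_fractions[[treatment]]
  }
  nb <- cfg$n_berries
  B <- length(grid$values)

  # fruit-level draws: shared across sides (same physical tray)
  fruit <- local_seed(derive_seed(seed, "fruit"), {
    geom <- .place_berries(cfg)
    severity <- if (mu_frac == 0) rep(0, nb)
                else .clipnorm(nb, mu_frac, 0.06, 0, 1)
    firm <- cfg$firmness_intercept - cfg$firmness_slope * severity +
      stats::rnorm(nb, 0, cfg$firmness_noise_sd)
    cap_dir <- stats::runif(nb, 0, 2 * pi)
    list(geom = geom, severity = severity, firmness = firm,
         cap_dir = cap_dir)
  })
  frac_target <- switch(side,
                        single = fruit$severity,
                        stem = pmin(1, fruit$severity *
                                      (2 / (1 + cfg$calyx_side_attenuation))),
                        calyx = fruit$severity *
                          (2 * cfg$calyx_side_attenuation /
                             (1 + cfg$calyx_side_attenuation)))

  labels <- matrix(0L, cfg$rows, cfg$cols)
  bruise_mask <- matrix(0L, cfg$rows, cfg$cols)
  for (k in seq_len(nb)) {
    cr <- fruit$geom$centers[k, 1]; cc <- fruit$geom$centers[k, 2]
    r <- fruit$geom$radii[k]
    rows <- (cr - r):(cr + r); cols <- (cc - r):(cc + r)
    disc <- outer((rows - cr)^2, (cols - cc)^2, `+`) <= r^2
    labels[rows, cols][disc] <- k
    f <- frac_target[k]
    if (f > 0) {
      # one-sided cap: take the pixels with the largest projection onto the
      # cap direction until the target fraction of the disc is covered
      ri <- which(disc, arr.ind = TRUE)
      proj <- (rows[ri[, 1]] - cr) * cos(fruit$cap_dir[k]) +
        (cols[ri[, 2]] - cc) * sin(fruit$cap_dir[k])
      n_br <- round(f * nrow(ri))
      if (n_br > 0) {
        top <- order(proj, decreasing = TRUE)[seq_len(n_br)]
        bruise_mask[cbind(rows[ri[top, 1]], cols[ri[top, 2]])] <- 1L
      }
    }
  }

  # true fraction with the calyx disc excluded (the countable pixels)
  r2 <- cfg$calyx_radius_px^2
  true_fraction <- vapply(seq_len(nb), function(k) {
    idx <- which(labels == k)
    rr <- (idx - 1L) %% cfg$rows + 1L
    cc <- (idx - 1L) %/% cfg$rows + 1L
    in_calyx <- (rr - fruit$geom$centers[k, 1])^2 +
      (cc - fruit$geom$centers[k, 2])^2 <= r2
    sum(bruise_mask[idx][!in_calyx]) / sum(!in_calyx)
  }, numeric(1))

  h_spec <- healthy_spectrum(grid)
  b_spec <- bruised_spectrum(grid)
  wl <- grid$values

  refl <- local_seed(derive_seed(seed, paste0("scene-", side)), {
    flat <- matrix(0.04, cfg$rows * cfg$cols, B)  # dark background
    idx <- which(labels > 0L)
    m <- numeric(length(idx))
    is_bruise <- bruise_mask[idx] == 1L
    m[is_bruise] <- .clipnorm(sum(is_bruise), cfg$mix_bruised_mean,
                              cfg$mix_bruised_sd, 0.02, 1)
    m[!is_bruise] <- .clipnorm(sum(!is_bruise), cfg$mix_healthy_mean,
                               cfg$mix_healthy_sd, 0, 0.6)
    px <- outer(1 - m, h_spec) + outer(m, b_spec)
    px <- px * stats::rnorm(length(idx), 1, 0.04)  # per-pixel albedo scale
    flat[idx, ] <- px
    # dark calyx spot: flat low reflectance across all bands
    for (k in seq_len(nb)) {
      cr <- fruit$geom$centers[k, 1]; cc <- fruit$geom$centers[k, 2]
      rows <- (cr - cfg$calyx_radius_px):(cr + cfg$calyx_radius_px)
      cols <- (cc - cfg$calyx_radius_px):(cc + cfg$calyx_radius_px)
      disc <- outer((rows - cr)^2, (cols - cc)^2, `+`) <= r2
      ci <- which(labels[rows, cols] == k & disc)
      gi <- (rep(cols, each = length(rows))[ci] - 1L) * cfg$rows +
        rep(rows, length(cols))[ci]
      flat[gi, ] <- 0.08
    }
    flat
  })

  # illumination field and sensor model; dataset_scale models an intensity
  # difference the white panel does not capture, so it survives calibration
  # (normalization is what removes it)
  illum <- 1 + cfg$illum_amplitude *
    (outer(seq_len(cfg$rows) / cfg$rows - 0.5,
           rep(1, cfg$cols)) * 0.5 +
       outer(rep(1, cfg$rows), seq_len(cfg$cols) / cfg$cols - 0.5))
  gain <- 3300 * (0.85 + 0.15 * exp(-((wl - 1300) / 400)^2))

  if (cfg$noise_sd > 0) {
    refl <- refl + local_seed(derive_seed(seed, paste0("noise-", side)),
                              stats::rnorm(length(refl), 0, cfg$noise_sd))
  }
  refl <- refl * cfg$dataset_scale
  span <- as.vector(illum) %o% gain  # (rows*cols) x B sensor span in DN
  dims <- c(cfg$rows, cfg$cols, B)
  raw_arr <- array(round(pmax(pmin(cfg$dark_level + refl * span,
                                   cfg$dn_max), 0)), dims)
  white_arr <- array(round(pmin(cfg$dark_level + span, cfg$dn_max)), dims)
  dark_arr <- array(cfg$dark_level, dims)

  truth <- list(labels = labels, bruise_mask = bruise_mask,
                centers = fruit$geom$centers, radii = fruit$geom$radii,
                true_fraction = true_fraction,
                severity = fruit$severity,
                firmness = fruit$firmness,
                treatment = as.character(treatment), side = side)
  list(raw = hypercube(raw_arr, grid, "raw"),
       white = hypercube(white_arr, grid, "white_ref"),
       dark = hypercube(dark_arr, grid, "dark_ref"),
       truth = truth)
}

#' Sample labeled pixel spectra directly from the phantom tissue model
#'
#' Draws single-pixel reflectance spectra of one tissue class exactly as
#' [make_scene()] renders them (healthy/bruised mixture weight, per-pixel
#' albedo scale, additive sensor noise), without building a scene. Useful
#' for classifier studies at controlled sample sizes.
#'
#' @param cfg A [phantom_config()].
#' @param class `"healthy"` or `"bruised"`.
#' @param n Number of spectra.
#' @param seed Integer seed.
#' @param grid Wavelength grid.
#' @return A `spectral_library` (reflectance, unnormalized).
#' @export
sample_pixel_spectra <- function(cfg, class = c("healthy", "bruised"), n,
                                 seed = 1,
                                 grid = make_wavelength_grid(950, 1650, 5)) {
  stopifnot(inherits(cfg, "phantom_config"), n >= 1)
  class <- match.arg(class)
  h <- healthy_spectrum(grid)
  b <- bruised_spectrum(grid)
  spectra <- local_seed(seed, {
    m <- if (class == "bruised") {
      .clipnorm(n, cfg$mix_bruised_mean, cfg$mix_bruised_sd, 0.02, 1)
    } else {
      .clipnorm(n, cfg$mix_healthy_mean, cfg$mix_healthy_sd, 0, 0.6)
    }
    px <- outer(1 - m, h) + outer(m, b)
    px <- px * stats::rnorm(n, 1, 0.04)
    px <- px + stats::rnorm(length(px), 0, cfg$noise_sd)
    pmax(px * cfg$dataset_scale, 0)
  })
  .new_spectral_library(spectra, rep(class, n), grid$values,
                        source_tag = paste0("phantom-", class))
}

#' Sample per-berry mean spectra for given bruise fractions
#'
#' The mean spectrum of a berry with bruise fraction `f` is the tissue
#' mixture with effective weight
#' `f * mix_bruised_mean + (1 - f) * mix_healthy_mean`, plus residual
#' per-berry noise at `noise_sd / sqrt(px_per_berry)` (pixel noise averages
#' down over the berry).
#'
#' @param cfg A [phantom_config()].
#' @param fractions Vector of true bruise fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @param px_per_berry Nominal pixel count per berry (default 600).
#' @param grid Wavelength grid.
#' @return Matrix of mean spectra, one row per fraction.
#' @export
sample_mean_spectra <- function(cfg, fractions, seed = 1,
                                px_per_berry = 600,
                                grid = make_wavelength_grid(950, 1650, 5)) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  h <- healthy_spectrum(grid)
  b <- bruised_spectrum(grid)
  m_eff <- fractions * cfg$mix_bruised_mean +
    (1 - fractions) * cfg$mix_healthy_mean
  X <- outer(1 - m_eff, h) + outer(m_eff, b)
  local_seed(seed,
             X * stats::rnorm(length(fractions), 1, 0.04 /
                                sqrt(px_per_berry)) +
               stats::rnorm(length(X), 0, cfg$noise_sd /
                              sqrt(px_per_berry)))
}

#' Simulate a parallel-plate force/deformation curve
#'
#' Samples at 0.01 mm steps over 0-3 mm: force is `slope * deformation`
#' plus Gaussian noise, with an optional compressive toe below 0.5 mm and a
#' plateau beyond 2.5 mm, mimicking where real curves leave the straight
#' regime.
#'
#' @param true_slope Underlying slope in N/mm.
#' @param noise_sd Force noise sd in N.
#' @param seed Integer seed.
#' @param nonlinear Add the toe/plateau distortions outside the 0.5-2.5 mm
#'   fitting window.
#' @return List with `deformation` (mm) and `force` (N), 301 samples.
#' @export
make_force_curve <- function(true_slope, noise_sd = 0.01, seed = 1,
                             nonlinear = TRUE) {
  stopifnot(true_slope > 0, noise_sd >= 0)
  d <- seq(0, 3, by = 0.01)
  f <- true_slope * d
  if (nonlinear) {
    toe <- d < 0.5
    f[toe] <- true_slope * d[toe]^2 / 0.5  # quadratic toe, continuous at 0.5
    plat <- d > 2.5
    f[plat] <- true_slope * (2.5 + 0.4 * (d[plat] - 2.5))
  }
  f <- f + local_seed(seed, stats::rnorm(length(d), 0, noise_sd))
  list(deformation = d, force = f)
}

#' Simulate human assessment of sliced fruit
#'
#' A grader sees only the central slice: the assessment is the bruised/total
#' pixel ratio along each berry's central slice line of the true bruise
#' mask, plus truncated Gaussian noise, clipped to `[0, 1]`. Bruises that
#' miss the slice are invisible to the grader by construction.
#'
#' @param truth Truth component of [make_scene()].
#' @param slice_axis `"row"` (default) or `"col"`: direction of the cut.
#' @param noise_sd Grader noise sd (default 0.08).
#' @param seed Integer seed.
#' @return Numeric vector of assessments in `[0, 1]`, one per berry.
#' @export
simulate_human_assessment <- function(truth, slice_axis = c("row", "col"),
                                      noise_sd = 0.08, seed = 1) {
  slice_axis <- match.arg(slice_axis)
  nb <- nrow(truth$centers)
  base <- vapply(seq_len(nb), function(k) {
    cr <- truth$centers[k, 1]; cc <- truth$centers[k, 2]
    sel <- if (slice_axis == "row") truth$labels[cr, ] == k
           else truth$labels[, cc] == k
    line_lab <- if (slice_axis == "row") truth$bruise_mask[cr, ]
                else truth$bruise_mask[, cc]
    sum(line_lab[sel]) / max(1, sum(sel))
  }, numeric(1))
  noisy <- base + local_seed(seed, stats::rnorm(nb, 0, noise_sd))
  pmin(1, pmax(0, noisy))
}
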