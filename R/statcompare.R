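# Statistical comparison suite: one-way MANOVA on spectra (Wilks' lambda,
# Rao F approximation), Kruskal-Wallis with Dunn-type joint-rank post-hoc
# comparisons and a compact letter display, linear regression of bruise
# ratio index against human assessment, and one-way ANOVA on bruised-fruit
# counts. All tests are two-tailed at alpha = 0.05 unless stated.

.test_result <- function(test, statistic, df, p_value, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value), extra),
            class = "hsib_test")
}

#' @export
print.hsib_test <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, df=%s, p=%.4g\n", x$test, x$statistic,
              paste(signif(unlist(x$df), 4), collapse = "/"), x$p_value))
  invisible(x)
}

#' One-way MANOVA comparing groups of spectra
#'
#' Wilks' lambda (`det(W)/det(W+B)`) with Rao's F approximation, each
#' wavelength one response variable. With `B` bands the test needs
#' `n - #groups > B`; smaller designs are rejected with guidance to
#' subsample bands (`band_step`).
#'
#' @param groups List of spectra matrices (same band count), one per group.
#' @param band_step Optional integer: use every `band_step`-th band to
#'   reduce dimensionality.
#' @return An `hsib_test` with fields `statistic` (Wilks' lambda), `f`,
#'   `df`, `p_value`.
#' @export
manova_spectra <- function(groups, band_step = 1) {
  stopifnot(is.list(groups), length(groups) >= 2)
  X <- do.call(rbind, groups)
  if (band_step > 1) X <- X[, seq(1, ncol(X), by = band_step), drop = FALSE]
  g <- factor(rep(seq_along(groups), vapply(groups, nrow, integer(1))))
  n <- nrow(X); k <- length(groups); p <- ncol(X)
  if (n - k <= p) {
    stop(sprintf(paste0(
      "MANOVA on %d variables needs n - groups > %d but n = %d; ",
      "subsample bands (band_step) or add samples"), p, p, n))
  }
  group_means <- rowsum(X, g) / as.vector(table(g))
  if (max(abs(sweep(group_means, 2, group_means[1, ]))) < 1e-12) {
    # identical group means: between-scatter is zero, lambda is exactly 1
    return(.test_result("manova_wilks", 1, list(df1 = p * (k - 1)), 1,
                        extra = list(f = 0)))
  }
  fit <- stats::manova(X ~ g)
  s <- summary(fit, test = "Wilks")$stats
  .test_result("manova_wilks",
               statistic = s[1, "Wilks"],
               df = list(df1 = s[1, "num Df"], df2 = s[1, "den Df"]),
               p_value = s[1, "Pr(>F)"],
               extra = list(f = s[1, "approx F"], n = n, p_vars = p))
}

#' Kruskal-Wallis rank test across treatment groups
#'
#' H statistic on joint ranks with tie correction and the chi-square
#' approximation (`df = groups - 1`).
#'
#' @param groups List of numeric vectors, one per treatment.
#' @return An `hsib_test`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all observations identical; H is undefined")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  .test_result("kruskal_wallis", statistic = unname(kt$statistic),
               df = list(df = unname(kt$parameter)),
               p_value = kt$p.value)
}

#' Dunn-type multiple comparisons with a compact letter display
#'
#' Pairwise two-sided z comparisons of mean joint ranks with tie correction,
#' Bonferroni-adjusted, assembled into letters: treatments sharing a letter
#' are not significantly different. Letters are inserted greedily over the
#' non-significance graph, smallest mean rank first.
#'
#' @param groups Named list of numeric vectors (names become treatment
#'   labels; unnamed lists get `g1`, `g2`, ...).
#' @param alpha Family significance level (default 0.05).
#' @return List with the omnibus `kruskal_wallis` result, a data.frame of
#'   pairwise comparisons (`z`, raw and adjusted p), and `letters`.
#' @export
kw_multcomp <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  omnibus <- kruskal_wallis(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- lengths(groups)
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[j] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- pmin(1, p_raw * m)  # Bonferroni
  cmp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = z, p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha)
  # non-significance adjacency
  nonsig <- matrix(TRUE, k, k, dimnames = list(names(groups), names(groups)))
  for (j in seq_len(m)) {
    if (cmp$significant[j]) {
      nonsig[pairs[1, j], pairs[2, j]] <- FALSE
      nonsig[pairs[2, j], pairs[1, j]] <- FALSE
    }
  }
  letters_out <- .compact_letters(nonsig, order(mean_ranks))
  list(omnibus = omnibus, comparisons = cmp, letters = letters_out,
       mean_ranks = mean_ranks, alpha = alpha)
}

# greedy insertion compact letter display: groups ordered (smallest mean
# first); each letter is a maximal clique grown along that order
.compact_letters <- function(nonsig, ord) {
  k <- nrow(nonsig)
  nm <- rownames(nonsig)
  sets <- list()
  for (i in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(nonsig[i, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], i)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- i
  }
  # drop letter sets wholly contained in another
  keep <- rep(TRUE, length(sets))
  for (s in seq_along(sets)) {
    for (t in seq_along(sets)) {
      if (s != t && keep[t] && all(sets[[s]] %in% sets[[t]]) &&
          length(sets[[s]]) < length(sets[[t]])) keep[s] <- FALSE
    }
  }
  sets <- sets[keep]
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  names(out) <- nm
  out
}

#' Linear regression of bruise ratio index on human assessment
#'
#' Ordinary least squares with intercept; reports slope, intercept,
#' coefficient of determination and RMSE (`sqrt(SS_res / n)`).
#'
#' @param x Human assessments (fractions).
#' @param y Bruise ratio indices (fractions).
#' @return List: `slope`, `intercept`, `r_squared`, `rmse`, `n`.
#' @export
linreg_index_vs_human <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("human assessments have zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       rmse = sqrt(ss_res / length(y)),
       n = length(y))
}

#' One-way ANOVA comparing bruised-fruit counts between methods
#'
#' Compares per-replicate bruised counts obtained from two (or more)
#' quantification methods within a treatment. Degenerate input with zero
#' variance everywhere and equal means returns `p = 1` by convention.
#'
#' @param counts_by_method List of numeric vectors of per-replicate counts,
#'   one per method.
#' @return An `hsib_test` with the F statistic and p-value.
#' @export
anova_counts <- function(counts_by_method) {
  stopifnot(is.list(counts_by_method), length(counts_by_method) >= 2)
  if (any(lengths(counts_by_method) < 2)) {
    stop("need at least 2 replicates per method")
  }
  x <- unlist(counts_by_method, use.names = FALSE)
  g <- factor(rep(seq_along(counts_by_method), lengths(counts_by_method)))
  means <- tapply(x, g, mean)
  if (stats::var(x) == 0) {
    message("all counts identical across methods; p = 1 by convention")
    return(.test_result("anova_counts", statistic = 0,
                        df = list(df1 = nlevels(g) - 1,
                                  df2 = length(x) - nlevels(g)),
                        p_value = 1))
  }
  fit <- stats::aov(x ~ g)
  s <- summary(fit)[[1]]
  .test_result("anova_counts", statistic = s[1, "F value"],
               df = list(df1 = s[1, "Df"], df2 = s[2, "Df"]),
               p_value = s[1, "Pr(>F)"],
               extra = list(means = as.vector(means)))
}
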