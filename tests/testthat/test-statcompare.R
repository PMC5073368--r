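test_that("Kruskal-Wallis H matches a brute-force rank computation", {
  groups <- list(c(1, 2, 3), c(4, 5, 6))
  # independent oracle: H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1), no ties
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  Rj <- c(sum(r[1:3]), sum(r[4:6]))
  H_oracle <- 12 / (N * (N + 1)) * sum(Rj^2 / c(3, 3)) - 3 * (N + 1)
  expect_equal(round(H_oracle, 3), 3.857)

  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, H_oracle, tolerance = 1e-10)
  expect_equal(res$df$df, 1)
})

test_that("H is invariant to within-group permutation and monotone maps", {
  g <- list(c(3, 1, 4, 1.5), c(5, 9, 2.6), c(5.3, 5.8, 9.7, 9.3))
  h0 <- kruskal_wallis(g)$statistic
  perm <- lapply(g, function(v) v[sample(length(v))])
  expect_equal(kruskal_wallis(perm)$statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) 3 * v + 1))$statistic, h0)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("Wilks' lambda is 1 exactly for duplicated groups", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40)
  res <- manova_spectra(list(X, X))
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1)
})

test_that("MANOVA detects a mean shift and respects its bounds", {
  set.seed(3)
  a <- matrix(rnorm(100 * 5), 100)
  b <- matrix(rnorm(100 * 5), 100)
  b[, 2] <- b[, 2] + 3
  res <- manova_spectra(list(a, b))
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$statistic, 0)
  expect_lte(res$statistic, 1)
})

test_that("MANOVA refuses designs with too few samples per variable", {
  set.seed(4)
  groups <- list(matrix(rnorm(10 * 20), 10), matrix(rnorm(10 * 20), 10))
  expect_error(manova_spectra(groups), "subsample")
  # band subsampling makes the same design feasible
  res <- manova_spectra(groups, band_step = 5)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("post-hoc letters separate distinct groups and join identical ones", {
  set.seed(5)
  far <- list(a = rnorm(20, 0, 0.1), b = rnorm(20, 5, 0.1),
              c = rnorm(20, 10, 0.1))
  l1 <- kw_multcomp(far)$letters
  expect_identical(unname(l1), c("a", "b", "c"))

  same <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  l2 <- kw_multcomp(same)$letters
  expect_identical(unname(l2), c("a", "a", "a"))
})

test_that("a monotone treatment effect separates control from bruise groups", {
  # drop-height-like design: control plus three increasingly bruised groups
  set.seed(6)
  mk <- function(mu) pmin(1, pmax(0, rnorm(25, mu, 0.08)))
  groups <- list(control = mk(0.02), h15 = mk(0.35), h23 = mk(0.5),
                 h31 = mk(0.65))
  res <- kw_multcomp(groups)
  letters_ <- res$letters
  expect_false(any(strsplit(letters_[["control"]], "")[[1]] %in%
                     unlist(strsplit(letters_[-1], ""))))
  expect_lt(res$omnibus$p_value, 0.001)
})

test_that("index-vs-human regression reports R2 and RMSE correctly", {
  x <- seq(0, 1, length.out = 20)
  fit <- linreg_index_vs_human(x, x)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0)
  expect_equal(fit$slope, 1)

  fit2 <- linreg_index_vs_human(x, -x)
  expect_equal(fit2$r_squared, 1)

  set.seed(7)
  y <- 0.3 + 0.5 * x + rnorm(20, 0, 0.05)
  fit3 <- linreg_index_vs_human(x, y)
  expect_true(fit3$r_squared > 0 && fit3$r_squared < 1)
  expect_equal(fit3$rmse, sqrt(sum(residuals(lm(y ~ x))^2) / 20))

  expect_error(linreg_index_vs_human(rep(0.5, 10), rnorm(10)), "variance")
  expect_error(linreg_index_vs_human(1:2, 1:2), "at least 3")
})

test_that("count ANOVA matches the squared two-sample t and handles ties", {
  a <- c(3, 5, 4, 6)
  b <- c(8, 9, 7, 10)
  res <- anova_counts(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)  # algebraic identity F = t^2
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  expect_equal(anova_counts(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(suppressMessages(
    anova_counts(list(c(2, 2), c(2, 2)))$p_value), 1)

  jit <- list(c(0, 0, 0, 0) + 1e-6 * (1:4), c(25, 25, 25, 25) + 1e-6 * (1:4))
  expect_lt(anova_counts(jit)$p_value, 1e-10)

  expect_error(anova_counts(list(1, 2)), "replicates")
})
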