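# Association layer: correlations, group tests, ddCt, densitometry.

test_that("correlate reproduces hand-computed r and enforces preconditions", {
  res <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$r_squared, 0.64)
  expect_equal(res$df, 2L)
  x <- 1:10
  perfect <- correlate(x, x * 2 + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p_value, 0)
  expect_error(correlate(1:10, rep(3, 10)), "degenerate")
  expect_error(correlate(1:2, 2:3), "at least 3")
})

test_that("correlate drops missing pairs and is symmetric in its coefficient", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 1, 10, 3, NA)
  res <- correlate(x, y)
  expect_equal(res$n, 3L)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(correlate(a, b)$r, correlate(b, a)$r, tolerance = 1e-12)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10)
    rho <- correlate(a, b, method = "spearman")$spearman_rho
    expect_equal(correlate(exp(a), b)$spearman_rho, rho, tolerance = 1e-12)
    expect_equal(correlate(a, b^3 + 5 * b)$spearman_rho, rho, tolerance = 1e-12)
  }
})

test_that("correlation p-value matches the exhaustive permutation null in rank order", {
  set.seed(13)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  p_perm <- perm_pvalue_exhaustive(x, y)
  p_t <- correlate(x, y)$p_value
  # n = 4: both must call this clearly non-significant
  expect_gt(p_perm, 0.05)
  expect_gt(p_t, 0.05)
  # rank agreement across instances: more extreme r => smaller p for both
  ps <- t(sapply(1:15, function(i) {
    a <- rnorm(6)
    b <- rnorm(6)
    c(t = correlate(a, b)$p_value, perm = perm_pvalue_exhaustive(a, b))
  }))
  expect_gt(cor(rank(ps[, "t"]), rank(ps[, "perm"])), 0.9)
})

test_that("group_ttest reports means, folds and matches the hand example", {
  res <- group_ttest(c(2, 4, 6, 1, 2, 3),
    factor(rep(c("up", "dn"), each = 3), levels = c("dn", "up")),
    variant = "pooled"
  )
  expect_equal(res$t_stat, 2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$fold_change, 2) # mean 4 over mean 2
  same <- group_ttest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_ttest(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Welch and pooled agree exactly for equal sizes and variances", {
  x <- c(1, 2, 3)
  y <- c(5, 6, 7) # equal variance, equal n
  w <- group_ttest(c(x, y), rep(c("a", "b"), each = 3), variant = "welch")
  p <- group_ttest(c(x, y), rep(c("a", "b"), each = 3), variant = "pooled")
  expect_equal(w$t_stat, p$t_stat, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-12)
})

test_that("ddCt fold follows 2^(-ddct) with conservation at equality", {
  expect_equal(fold_change_ddct(25, 20, 24, 19)$fold, 1) # both dCt = 5
  # dCt_treat = 5, dCt_ctrl = 4 -> fold 0.5
  expect_equal(fold_change_ddct(25, 20, 24, 20)$fold, 0.5)
  # target one cycle lower in treatment, housekeepers unchanged -> fold 2
  expect_equal(fold_change_ddct(23, 20, 24, 20)$fold, 2)
  expect_error(fold_change_ddct(numeric(0), 20, 24, 20), "empty")
  set.seed(17)
  for (i in 1:20) { # conservation for arbitrary symmetric inputs
    a <- rnorm(3, 25)
    b <- rnorm(3, 20)
    expect_equal(fold_change_ddct(a, b, a, b)$fold, 1, tolerance = 1e-12)
  }
})

test_that("ddCt propagates replicate SD into a fold range", {
  res <- fold_change_ddct(c(25, 25.4), c(20, 20.2), c(24, 24.2), c(20, 19.8))
  expect_true(res$fold_lo < res$fold && res$fold < res$fold_hi)
  expect_equal(res$sd_ddct,
    sqrt(sum(c(0.08, 0.02, 0.02, 0.02) / 2)),
    tolerance = 1e-12
  )
})

test_that("densitometry normalization maps the control to 1 and is scale-invariant", {
  expect_equal(densitometry_normalize(100, 100, 100, 100), 1)
  expect_equal(densitometry_normalize(50, 100, 100, 100), 0.5)
  expect_error(densitometry_normalize(0, 1, 1, 1), "positive")
  set.seed(19)
  for (i in 1:20) {
    v <- rlnorm(4, 5)
    c0 <- runif(1, 0.1, 10)
    expect_equal(
      densitometry_normalize(v[1], v[2], v[3], v[4]),
      densitometry_normalize(c0 * v[1], c0 * v[2], c0 * v[3], c0 * v[4]),
      tolerance = 1e-12
    )
  }
})
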