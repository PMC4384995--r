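test_that("spearman rho equals Pearson on mid-ranks and handles ties", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(1:4, c(40, 30, 20, 10))$rho, -1)
  set.seed(2)
  for (i in 1:10) {
    x <- sample(1:6, 8, replace = TRUE) # ties likely
    y <- rnorm(8)
    expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)))
    expect_equal(spearman(x, y)$rho,
                 suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]])
  }
  expect_true(is.na(spearman(rep(1, 5), rnorm(5))$rho))
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("spearman is antisymmetric in y and invariant to pair order", {
  set.seed(8)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman(x, -y)$rho, -spearman(x, y)$rho)
  p <- sample(7)
  expect_equal(spearman(x[p], y[p])$rho, spearman(x, y)$rho)
})

test_that("exact permutation p matches the independent exact oracle and the t approximation converges", {
  set.seed(14)
  # tie-free data: full enumeration must reproduce the classical exact
  # null distribution (cor.test's AS 89 path) to machine precision
  for (n in 5:9) {
    x <- rnorm(n); y <- rnorm(n)
    exact <- spearman(x, y, exact_max = 9)
    expect_equal(exact$method, "exact-permutation")
    expect_equal(exact$p_value,
                 cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # the t approximation approaches the exact p as n grows; by the n = 8/9
  # crossover the two paths agree to ~0.03 (the exact null is discrete with
  # coarse granularity at n = 5, where gaps up to ~0.08 remain)
  dev_by_n <- vapply(c(5L, 8L), function(n) {
    mean(replicate(40, {
      x <- rnorm(n); y <- rnorm(n)
      abs(spearman(x, y, exact_max = 9)$p_value -
            spearman(x, y, exact_max = 0)$p_value)
    }))
  }, numeric(1))
  expect_lt(dev_by_n[2], dev_by_n[1])
  expect_lt(dev_by_n[2], 0.02)
})

test_that("mann_whitney_u exact small-sample cases", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact")
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("mann_whitney_u is symmetric and shift-invariant", {
  set.seed(4)
  a <- rnorm(5); b <- rnorm(6, 1)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$u_statistic + r2$u_statistic, 30) # U_a + U_b = n1 n2
  r3 <- mann_whitney_u(a + 17, b + 17)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$u_statistic, r1$u_statistic)
})

test_that("mann_whitney_u exact path matches wilcox.test and the approximation is close", {
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.8)
    exact <- mann_whitney_u(a, b)
    expect_equal(exact$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
    approx <- mann_whitney_u(a, b, exact_max = 0)
    expect_equal(approx$method, "normal-approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.03)
  }
})

test_that("ks_normality retains normal samples and rejects exponential ones", {
  set.seed(19)
  x <- rnorm(500)
  e <- rexp(500)
  expect_gt(ks_normality(x)$p_value, 0.05)
  expect_lt(ks_normality(e)$p_value, 0.01)
  # statistic equals the direct ECDF scan (plain KS with estimated moments)
  for (v in list(x[1:40], e[1:40])) {
    d_scan <- suppressWarnings(
      ks.test(v, "pnorm", mean(v), sd(v))$statistic[[1]])
    expect_equal(ks_normality(v)$statistic, d_scan, tolerance = 1e-12)
  }
  expect_equal(ks_normality(rep(2, 10))$p_value, 0)
  lil <- ks_normality(x[1:50], "lilliefors")
  plain <- ks_normality(x[1:50], "plain")
  expect_equal(lil$statistic, plain$statistic)
  expect_lte(lil$p_value, plain$p_value + 1e-9) # correction is less forgiving
})
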