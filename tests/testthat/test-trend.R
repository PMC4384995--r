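test_that("pava_isotonic pools violators and preserves the weighted mean", {
  expect_equal(pava_isotonic(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava_isotonic(c(3, 1)), c(2, 2))
  expect_equal(pava_isotonic(c(1, 3), direction = "decrease"), c(2, 2))

  set.seed(11)
  for (i in 1:25) {
    m <- rnorm(6)
    w <- runif(6, 0.5, 4)
    fit <- pava_isotonic(m, w)
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(sum(w * fit), sum(w * m), tolerance = 1e-9)
  }
})

test_that("pava_isotonic agrees with the exhaustive monotone-partition oracle", {
  set.seed(21)
  for (i in 1:60) {
    m <- rnorm(6)
    w <- if (i %% 2) rep(1, 6) else runif(6, 0.5, 3)
    expect_equal(pava_isotonic(m, w), pava_oracle(m, w), tolerance = 1e-9)
  }
})

test_that("Monte-Carlo reference values are cached, deterministic, and reduce to Student t", {
  n <- c(4, 4, 4)
  cv1 <- williams_critical_value(n, 0.025, "williams", nrep = 5000)
  cv2 <- williams_critical_value(n, 0.025, "williams", nrep = 5000)
  expect_identical(cv1, cv2)
  # single-dose design: the statistic is an ordinary one-sided two-sample t
  expect_equal(williams_critical_value(c(8, 8), 0.025, "williams"),
               qt(0.975, 14))
  # amalgamation shrinks the maximum below the Dunnett-free two-group case,
  # but the reference must still exceed the plain t quantile's alpha mate
  expect_gt(cv1, qt(0.95, sum(n) - 3))
})

test_that("williams_test rejects overwhelming trends and nothing on constants", {
  og_const <- ordered_groups(rep(5, 4), list(a = rep(5, 4), b = rep(5, 4)))
  res <- williams_test(og_const)
  expect_false(any(res$stages$reject))

  set.seed(42)
  og <- ordered_groups(rnorm(10), list(w1 = rnorm(10, 0.1),
                                       w2 = rnorm(10, 0.2),
                                       w3 = rnorm(10, 0.5),
                                       w4 = rnorm(10, 5)))
  res <- williams_test(og, nrep = 20000)
  expect_true(res$stages$reject[res$stages$group == "w4"])
  expect_error(williams_test(ordered_groups(1, list(a = c(1, 2)))),
               ">= 2 observations")
})

test_that("step-down rejections form a contiguous suffix of the ordering", {
  set.seed(5)
  for (i in 1:15) {
    og <- ordered_groups(rnorm(5), lapply(1:4, function(k) {
      rnorm(5, mean = sample(c(0, 0.5, 2), 1))
    }))
    for (fit in list(williams_test(og, nrep = 5000),
                     shirley_williams_test(og, nrep = 5000))) {
      rej <- rev(fit$stages$reject) # dose order, lowest first
      expect_true(all(diff(rej) >= 0),
                  info = "a rejected group below a non-rejected one")
    }
  }
})

test_that("shirley_williams_test detects monotone shifts and is rank-invariant", {
  set.seed(9)
  shift <- lapply(1:4, function(k) rnorm(8, mean = 0.75 * k))
  og <- ordered_groups(rnorm(8), shift)
  res <- shirley_williams_test(og, nrep = 20000)
  expect_true(res$stages$reject[1])

  og_const <- ordered_groups(rep(1, 4), list(a = rep(1, 4), b = rep(1, 4)))
  expect_false(any(shirley_williams_test(og_const)$stages$reject))

  # invariance under a strictly monotone transformation of all observations
  tr <- function(x) exp(3 * x) - 1
  og_tr <- ordered_groups(tr(og$control), lapply(og$groups, tr))
  res_tr <- shirley_williams_test(og_tr, nrep = 20000)
  expect_equal(res_tr$stages$statistic, res$stages$statistic,
               tolerance = 1e-12)
  expect_identical(res_tr$stages$reject, res$stages$reject)
})

test_that("decreasing direction mirrors increasing on negated data", {
  set.seed(31)
  og <- ordered_groups(rnorm(6), lapply(1:3, function(k) rnorm(6, -k)))
  og_neg <- ordered_groups(-og$control, lapply(og$groups, function(g) -g))
  down <- williams_test(og, direction = "decrease", nrep = 10000)
  up <- williams_test(og_neg, direction = "increase", nrep = 10000)
  expect_equal(down$stages$statistic, up$stages$statistic, tolerance = 1e-12)
})
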