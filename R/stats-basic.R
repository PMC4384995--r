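# All-permutations matrix of 1..n (n! x n), built recursively.
# Used only for exact permutation p-values at small n.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of the mid-rank vectors (ties share their
#' average rank). The two-sided p-value is computed by full permutation
#' enumeration for n <= `exact_max` (the null distribution of rho given the
#' observed tie patterns), and otherwise by the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact_max Largest n for which the exact permutation path is used.
#' @return List with `rho`, `p_value` (two-sided), `n` and `method`
#'   (`"exact-permutation"` or `"t-approximation"`). A constant input vector
#'   leaves rho undefined: `rho` and `p_value` are `NA`.
#' @export
spearman <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined-constant-input"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    # rho for a permuted ry differs from rho only through sum(rx * ry_perm),
    # so the whole null distribution is one matrix product
    perms <- .permutations(n)
    s_null <- matrix(ry[perms], nrow(perms), n) %*% rx
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rho_null <- (s_null - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# U statistic of sample a vs b from joint mid-ranks.
.u_stat <- function(a, b) {
  rk <- rank(c(a, b))
  sum(rk[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test, exact by enumeration for small samples
#'
#' Two-sided test of identical distributions against a location shift. For
#' `n1 + n2 <= exact_max` the exact p-value is computed by enumerating all
#' choose(n1+n2, n1) group labelings of the pooled sample (mid-ranks within
#' each labeling, so ties are handled inside the enumeration); the two-sided
#' p is the null probability of a U at least as far from its mean n1 n2 / 2
#' as observed. For larger samples a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact_max Largest pooled size for the exact path.
#' @return List with `u_statistic` (for sample `a`), `p_value`, `n` =
#'   `c(n1, n2)` and `method` (`"exact"` or `"normal-approximation"`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 14L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L, !anyNA(a), !anyNA(b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    sel <- utils::combn(N, n1)
    rsum <- colSums(matrix(rk[sel], nrow = n1))
    u_null <- rsum - n1 * (n1 + 1) / 2
    p <- mean(abs(u_null - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal-approximation"
  }
  list(u_statistic = u, p_value = p, n = c(n1, n2), method = method)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal distribution with
#' mean and SD estimated from the same data,
#' `D = max |ECDF - fitted normal CDF|`. Because the parameters are
#' estimated, the plain KS null distribution is anticonservative; the
#' default p-value therefore uses the Lilliefors correction
#' (via `nortest::lillie.test`), with the plain-KS p available by flag (both
#' are labeled in the result). Constant data are degenerate and reported as
#' non-normal (p = 0).
#'
#' @param values Numeric vector, n >= 5.
#' @param p_method `"lilliefors"` (default) or `"plain"`.
#' @return List with `statistic`, `p_value`, `n`, `p_method`.
#' @export
ks_normality <- function(values, p_method = c("lilliefors", "plain")) {
  p_method <- match.arg(p_method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = 0, n = n,
                p_method = "degenerate-constant"))
  }
  z <- sort((values - mean(values)) / stats::sd(values))
  cdf <- stats::pnorm(z)
  d <- max(pmax(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n))
  p <- if (p_method == "lilliefors") {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  }
  list(statistic = d, p_value = p, n = n, p_method = p_method)
}
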