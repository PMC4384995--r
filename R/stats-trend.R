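#' Weighted isotonic regression by pool-adjacent-violators
#'
#' Solves min sum w_i (x_i - m_i)^2 over monotone m (non-decreasing for
#' `direction = "increase"`), the amalgamation step of Williams-type trend
#' tests. The solution is piecewise constant on blocks whose values are the
#' weighted block means, so the weighted grand mean is preserved.
#'
#' @param means Numeric vector of group means (or mean ranks).
#' @param weights Positive weights, usually group sizes.
#' @param direction `"increase"` or `"decrease"`.
#' @return Numeric vector of amalgamated values, monotone in `direction`.
#' @export
pava_isotonic <- function(means, weights = rep(1, length(means)),
                          direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(length(means) == length(weights), all(weights > 0),
            !anyNA(means))
  if (direction == "decrease") {
    return(-pava_isotonic(-means, weights, "increase"))
  }
  k <- length(means)
  # blocks as (value, weight, size) stacks; classic PAVA sweep
  val <- numeric(k); wt <- numeric(k); sz <- integer(k)
  nb <- 0L
  for (i in seq_len(k)) {
    nb <- nb + 1L
    val[nb] <- means[i]; wt[nb] <- weights[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      w <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / w
      wt[nb - 1L] <- w
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], sz[seq_len(nb)])
}

# Amalgamated mean at the top of an increasing ordering equals
# max over s of the weighted mean of groups s..k; used to vectorize the
# Monte-Carlo null below (independent of the PAVA sweep above).
.top_amalgamated <- function(means_mat, weights) {
  k <- length(weights)
  out <- matrix(NA_real_, nrow(means_mat), k)
  wsum <- rev(cumsum(rev(weights)))
  acc <- 0
  for (s in k:1) {
    acc <- acc + means_mat[, s] * weights[s]
    out[, k - s + 1L] <- acc / wsum[s]
  }
  do.call(pmax, as.data.frame(out))
}

# Cache of Monte-Carlo reference values, keyed by design + method.
.cv_cache <- new.env(parent = emptyenv())

#' Monte-Carlo reference value for Williams-type step-down statistics
#'
#' Upper quantile of the null distribution of the maximum-stage statistic
#' t-bar_k for a control + k ordered groups design. For
#' `method = "williams"` the statistic uses group means amalgamated by
#' isotonic regression and a pooled variance on `sum(n) - (k+1)` degrees of
#' freedom. For `method = "shirley"` the rank analog is simulated from
#' continuous null data (the rank statistic is distribution-free). For
#' `k = 1` the Williams statistic reduces to an ordinary one-sided two-sample
#' t, and the exact `qt` quantile is returned, which also serves as an
#' internal cross-check of the simulation machinery.
#'
#' Results are deterministic (a fixed internal seed stream, independent of
#' the caller's RNG) and cached per (k, n-vector, alpha, method, nrep).
#'
#' @param n Integer vector of group sizes `c(n0, n1, ..., nk)` (control
#'   first).
#' @param alpha One-sided significance level.
#' @param method `"williams"` or `"shirley"`.
#' @param nrep Number of null replicates for the quantile estimate.
#' @return Scalar reference value.
#' @export
williams_critical_value <- function(n, alpha = 0.025,
                                    method = c("williams", "shirley"),
                                    nrep = 50000L) {
  method <- match.arg(method)
  stopifnot(length(n) >= 2L, all(n >= 2L), alpha > 0, alpha < 0.5)
  k <- length(n) - 1L
  df <- sum(n) - length(n)
  if (k == 1L && method == "williams") {
    return(stats::qt(1 - alpha, df))
  }
  key <- paste(method, paste(n, collapse = "."), alpha, nrep, sep = "_")
  if (!is.null(.cv_cache[[key]])) return(.cv_cache[[key]])

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed((sum(n) * 1009L + k * 101L + round(alpha * 1e4) +
              (method == "shirley") * 7919L) %% .Machine$integer.max)

  w <- n[-1L]
  if (method == "williams") {
    # Only group means and the pooled variance enter the statistic.
    m0 <- stats::rnorm(nrep, 0, 1 / sqrt(n[1L]))
    mg <- matrix(stats::rnorm(nrep * k), nrep, k)
    mg <- sweep(mg, 2L, sqrt(w), "/")
    s2 <- stats::rchisq(nrep, df) / df
    top <- .top_amalgamated(mg, w)
    tbar <- (top - m0) / sqrt(s2 * (1 / n[length(n)] + 1 / n[1L]))
  } else {
    N <- sum(n)
    gidx <- rep(seq_along(n), n)
    # continuous null data are tie-free, so the rank variance is the
    # constant N(N+1)/12 (matching var(rank) in the test statistic)
    v <- N * (N + 1) / 12
    R <- apply(matrix(stats::rnorm(N * nrep), N, nrep), 2L, rank)
    M <- rowsum(R, gidx) / n # (k+1) x nrep mean ranks
    top <- .top_amalgamated(t(M[-1L, , drop = FALSE]), w)
    tbar <- (top - M[1L, ]) / sqrt(v * (1 / n[length(n)] + 1 / n[1L]))
  }
  cv <- stats::quantile(tbar, 1 - alpha, names = FALSE, type = 8)
  .cv_cache[[key]] <- cv
  cv
}

#' Assemble ordered-group data for trend testing
#'
#' @param control Numeric vector, the time-0 / zero-dose group.
#' @param groups Named list of numeric vectors ordered by increasing
#'   dose/time.
#' @return Object of class `ordered_groups`.
#' @export
ordered_groups <- function(control, groups) {
  stopifnot(is.numeric(control), length(control) >= 1L,
            is.list(groups), length(groups) >= 1L,
            all(vapply(groups, length, integer(1L)) >= 1L))
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  structure(list(control = control, groups = groups),
            class = "ordered_groups")
}

.trend_result <- function(stages, method, direction, alpha) {
  structure(list(stages = stages, method = method, direction = direction,
                 alpha = alpha, sided = "one-tailed"),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("%s test (step-down, one-tailed alpha = %g, direction = %s)\n",
              x$method, x$alpha, x$direction))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Williams' step-down trend test
#'
#' Tests for a monotone shift of ordered groups away from a control: at stage
#' k the highest-group amalgamated (isotonic) mean is compared to the control
#' mean via
#' \deqn{\bar t_k = (\hat M_k - \bar x_0) / \sqrt{s^2 (1/n_k + 1/n_0)}}
#' with `s^2` the pooled within-group variance over all groups. Testing
#' steps down from the highest group and stops at the first non-rejection,
#' so rejections always form a contiguous suffix of the ordering. Reference
#' values come from [williams_critical_value()]. With zero pooled variance
#' the data are degenerate constants and decisions fall back to exact
#' comparison of means.
#'
#' @param data An [ordered_groups()]; every group needs >= 2 observations.
#' @param direction `"increase"` (shift up from control) or `"decrease"`.
#' @param alpha One-sided significance level (conventionally 0.025).
#' @param nrep Monte-Carlo replicates for reference values.
#' @return A `trend_test_result`; `$stages` has one row per group (highest
#'   first) with the statistic, reference value and rejection decision
#'   (`NA` statistic for stages not reached).
#' @export
williams_test <- function(data, direction = c("increase", "decrease"),
                          alpha = 0.025, nrep = 50000L) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "ordered_groups"))
  gl <- c(list(control = data$control), data$groups)
  n <- vapply(gl, length, integer(1L))
  if (any(n < 2L)) {
    stop("every group needs >= 2 observations for variance pooling",
         call. = FALSE)
  }
  k <- length(gl) - 1L
  df <- sum(n) - length(gl)
  means <- vapply(gl, mean, numeric(1L))
  s2 <- sum(vapply(gl, function(g) sum((g - mean(g))^2), numeric(1L))) / df
  sgn <- if (direction == "increase") 1 else -1
  gm <- sgn * means[-1L] # work on the "increase" scale internally
  m0 <- sgn * means[1L]
  w <- n[-1L]

  stages <- data.frame(group = rev(names(data$groups)),
                       statistic = NA_real_, reference = NA_real_,
                       reject = NA)
  go <- TRUE
  for (kk in k:1) {
    row <- k - kk + 1L
    if (!go) break
    amal <- pava_isotonic(gm[seq_len(kk)], w[seq_len(kk)], "increase")
    if (s2 > 0) {
      tbar <- (amal[kk] - m0) / sqrt(s2 * (1 / n[kk + 1L] + 1 / n[1L]))
      cv <- williams_critical_value(n[seq_len(kk + 1L)], alpha, "williams",
                                    nrep)
      rej <- tbar > cv
      stages$statistic[row] <- tbar
      stages$reference[row] <- cv
    } else {
      rej <- amal[kk] > m0 # degenerate constants: exact comparison
    }
    stages$reject[row] <- rej
    go <- rej
  }
  stages$reject[is.na(stages$reject)] <- FALSE
  .trend_result(stages, "Williams", direction, alpha)
}

#' Shirley-Williams' step-down rank trend test
#'
#' Nonparametric analog of [williams_test()]: at each step-down stage the
#' observations of the groups still in play (control plus groups 1..k) are
#' re-ranked jointly with mid-ranks for ties, dose-group mean ranks are
#' amalgamated by isotonic regression, and
#' \deqn{\bar t_k = (\hat R_k - \bar R_0) / \sqrt{V (1/n_k + 1/n_0)}}
#' where `V` is the variance of the ranks in play (equal to N(N+1)/12 for
#' untied data, automatically tie-corrected otherwise). Reference values are
#' simulated rank-null quantiles, so the test is exact in distribution for
#' continuous data and invariant under monotone transformations.
#'
#' @inheritParams williams_test
#' @return A `trend_test_result` (see [williams_test()]).
#' @export
shirley_williams_test <- function(data, direction = c("increase", "decrease"),
                                  alpha = 0.025, nrep = 50000L) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "ordered_groups"))
  gl <- c(list(control = data$control), data$groups)
  n <- vapply(gl, length, integer(1L))
  if (any(n < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  k <- length(gl) - 1L
  sgn <- if (direction == "increase") 1 else -1

  stages <- data.frame(group = rev(names(data$groups)),
                       statistic = NA_real_, reference = NA_real_,
                       reject = NA)
  go <- TRUE
  for (kk in k:1) {
    row <- k - kk + 1L
    if (!go) break
    vals <- sgn * unlist(gl[seq_len(kk + 1L)], use.names = FALSE)
    gidx <- rep(seq_len(kk + 1L), n[seq_len(kk + 1L)])
    rk <- rank(vals) # mid-ranks for ties
    v <- stats::var(rk)
    mr <- vapply(split(rk, gidx), mean, numeric(1L))
    if (v > 0) {
      amal <- pava_isotonic(mr[-1L], n[2:(kk + 1L)], "increase")
      tbar <- (amal[kk] - mr[1L]) / sqrt(v * (1 / n[kk + 1L] + 1 / n[1L]))
      cv <- williams_critical_value(n[seq_len(kk + 1L)], alpha, "shirley",
                                    nrep)
      rej <- tbar > cv
      stages$statistic[row] <- tbar
      stages$reference[row] <- cv
    } else {
      rej <- FALSE # all observations tied: no evidence of trend
    }
    stages$reject[row] <- rej
    go <- rej
  }
  stages$reject[is.na(stages$reject)] <- FALSE
  .trend_result(stages, "Shirley-Williams", direction, alpha)
}
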