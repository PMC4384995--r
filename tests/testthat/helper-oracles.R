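# Independent brute-force oracles used across the suite.

# Isotonic regression by exhaustive search over all contiguous block
# partitions (2^(k-1) compositions): fitted vector is blockwise weighted
# means; keep monotone candidates; return the minimum weighted-SSE fit.
pava_oracle <- function(means, weights, direction = "increase") {
  if (direction == "decrease") {
    return(-pava_oracle(-means, weights, "increase"))
  }
  k <- length(means)
  best <- NULL
  best_sse <- Inf
  for (code in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(k - 2))) > 0)
    bounds <- c(0, cuts, k)
    fit <- numeric(k)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(means[idx] * weights[idx]) / sum(weights[idx])
    }
    if (any(diff(fit) < -1e-12)) next
    sse <- sum(weights * (means - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings of the
# pooled sample, computing U by direct pairwise comparison counting
# (ties count 1/2) -- a different computational path than the rank-sum
# formula used by the implementation.
mwu_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  u_of <- function(xa, xb) {
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  mu <- n1 * (N - n1) / 2
  obs <- abs(u_of(a, b) - mu)
  sel <- utils::combn(N, n1)
  stat <- apply(sel, 2, function(id) {
    abs(u_of(pooled[id], pooled[-id]) - mu)
  })
  mean(stat >= obs - 1e-9)
}

# Degradation series data frame from week means (weeks 1..4 or 1..3).
weekly_df <- function(means, weeks = seq_along(means)) {
  data.frame(week = weeks, mean = means)
}
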