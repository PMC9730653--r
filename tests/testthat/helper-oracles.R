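# Independent brute-force oracles. Each is written from the definition
# of the quantity, not by calling the implementation under test.

# two-sided rank-sum p by exhaustive enumeration of group assignments:
# W = rank sum of group 1; p = share of assignments with |W - E[W]|
# at least the observed deviation (E[W] = n1 (N + 1) / 2)
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  n <- length(r)
  e_w <- n1 * (n + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, function(idx) sum(r[idx]))
  mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# upper-tail hypergeometric probability as an explicit binomial sum
oracle_hyper_p <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# BH step-up written from the definition, with monotonicity enforced
# by a backwards cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# exact percentile interval of the bootstrap-mean distribution for
# tiny n: enumerate all n^n equally likely resamples and take the
# distribution quantile Q(p) = smallest value with cdf >= p
oracle_boot_exhaustive <- function(values, level = 0.95) {
  n <- length(values)
  grids <- do.call(expand.grid, rep(list(seq_len(n)), n))
  means <- sort(apply(grids, 1, function(idx) mean(values[idx])))
  qd <- function(p) means[which(seq_along(means) / length(means) >= p)[1]]
  alpha <- (1 - level) / 2
  c(lo = qd(alpha), hi = qd(1 - alpha))
}
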