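# Independent oracles used across the suite. These deliberately re-derive the
# statistics with naive enumeration / closed forms, separate from the package's
# computation paths.

# Kendall tau-a by explicit pair enumeration.
tau_a_oracle <- function(x, y) {
  m <- length(x)
  net <- 0L
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx != 0 && dy != 0) net <- net + ifelse((dx > 0) == (dy > 0), 1L, -1L)
  }
  net / (m * (m - 1) / 2)
}

# Exact one-sided upper-tail signed-rank p by enumeration of all 2^n sign
# patterns (valid with or without ties among |v|).
wilcoxon_exact_oracle <- function(v) {
  v <- v[v != 0]
  n <- length(v)
  rk <- rank(abs(v))
  W_obs <- sum(rk[v > 0])
  bits <- outer(0:(2^n - 1), 2^(seq_len(n) - 1),
                function(a, b) bitwAnd(a, b) > 0)
  W_all <- as.numeric(bits %*% rk)
  mean(W_all >= W_obs - 1e-12)
}

# Exact one-sided signed-rank p by generating-function convolution over
# doubled (possibly tied) ranks; cross-validated against the 2^n enumeration
# oracle at small n inside the tests, then used where enumeration is
# infeasible.
wilcoxon_conv_oracle <- function(v) {
  v <- v[v != 0]
  rk2 <- round(2 * rank(abs(v)))
  W2 <- round(2 * sum(rank(abs(v))[v > 0]))
  f <- c(1, rep(0, sum(rk2)))
  for (r in rk2) f <- f + c(rep(0, r), f[seq_len(length(f) - r)])
  sum(f[(seq_along(f) - 1) >= W2 - 1e-9]) / 2^length(v)
}

# Exact stimulus-label randomization distribution of tau-a for small n:
# tau over all n! simultaneous row/column permutations of b.
randomization_exact_oracle <- function(a, b) {
  n <- nrow(a)
  perms <- gtools_permutations(n)
  av <- a[lower.tri(a)]
  apply(perms, 1, function(p) {
    pb <- b[p, p]
    tau_a_oracle(av, pb[lower.tri(pb)])
  })
}

# All permutations of 1..n (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# A random valid RDM with distinct off-diagonal values.
random_rdm <- function(n, seed = NULL, labels = sprintf("o%02d", seq_len(n))) {
  rsacodes:::with_seed(seed, {
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
    d <- d + t(d)
    rdm(d, labels = labels, measure = "other")
  })
}
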