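# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity from its definition, not via the package's code
# paths.

# mean silhouette width from the O(N^2) pairwise-distance definition;
# singleton clusters contribute 0
silhouette_bruteforce <- function(X, labels) {
  D <- as.matrix(dist(X))
  mean(vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(c) mean(D[i, labels == c]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# BH step-up enumeration: adjusted p_(i) = min_{j >= i} m p_(j) / j, capped
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# exact two-sided rank-sum p by exhaustive enumeration of all rank splits
ranksum_exact_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  u_all <- apply(splits, 2, function(s) sum(seq_len(n)[s]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}
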