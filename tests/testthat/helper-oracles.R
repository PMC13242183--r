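# Independent brute-force oracles, deliberately written in plain R with
# explicit loops and full sorts, sharing no code with the package
# implementations they check.

# Relief/ReliefF by exhaustive pairwise distances and explicit sorting.
relieff_oracle <- function(x, y, k) {
  n <- nrow(x)
  m <- ncol(x)
  rng <- apply(x, 2, function(col) max(col) - min(col))
  diff_am <- function(a, i, j) {
    if (rng[a] == 0) 0 else abs(x[i, a] - x[j, a]) / rng[a]
  }
  dist_ij <- function(i, j) {
    s <- 0
    for (a in seq_len(m)) s <- s + diff_am(a, i, j)
    s
  }
  w <- numeric(m)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    d <- vapply(others, function(j) dist_ij(i, j), numeric(1))
    ord <- others[order(d, others)]
    hits <- ord[y[ord] == y[i]][seq_len(k)]
    misses <- ord[y[ord] != y[i]][seq_len(k)]
    for (a in seq_len(m)) {
      hit_diff <- mean(vapply(hits, function(j) diff_am(a, i, j), numeric(1)))
      miss_diff <- mean(vapply(misses, function(j) diff_am(a, i, j), numeric(1)))
      w[a] <- w[a] - hit_diff / n + miss_diff / n
    }
  }
  w
}

# AUROC by explicit enumeration of positive/negative pairs.
auroc_oracle <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all
# choose(nA+nB, nA) rank assignments (tie-free data only).
mann_whitney_exact_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  u_stat <- function(xa, xb) {
    u <- 0
    for (p in xa) for (q in xb) u <- u + (p > q)
    u
  }
  u_obs <- u_stat(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  mu <- na * nb / 2
  # two-sided: permutations at least as extreme (in |U - mean|) as observed
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# Pearson correlation from the definition (covariance over sd products).
pearson_oracle <- function(x) {
  m <- ncol(x)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    xi <- x[, i] - mean(x[, i])
    xj <- x[, j] - mean(x[, j])
    out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}
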