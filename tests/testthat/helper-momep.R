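# small fixtures shared across test files

# well-separated two-class feature table (first feature carries the signal)
separable_features <- function(n = 120, m = 4, shift = 3, seed = 42) {
  sim_features(n = n, m = m, class_mean_shift = c(shift, rep(0, m - 1)),
               seed = seed)
}

# population moments computed straight from the definitions, as the
# independent oracle for compute_moments()
oracle_moments <- function(px) {
  px <- as.numeric(px)
  mu <- sum(px) / length(px)
  v <- sum((px - mu)^2) / length(px)
  c(mean = mu, sd = sqrt(v),
    skewness = if (v > 0) (sum((px - mu)^3) / length(px)) / v^1.5 else 0,
    kurtosis = if (v > 0) (sum((px - mu)^4) / length(px)) / v^2 - 3 else 0,
    min = min(px), max = max(px))
}

# O(n^2) brute-force dominance ranks (maximization)
oracle_dominance_ranks <- function(objs) {
  n <- nrow(objs)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      i != j && all(objs[j, ] >= objs[i, ]) && any(objs[j, ] > objs[i, ])
    }, logical(1)))
  }, integer(1))
}

# Mann-Whitney pair-counting AUC (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]
  neg <- scores[labels <= 0]
  if (length(pos) == 0 || length(neg) == 0) return(0.5)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Friedman chi-squared recomputed from scratch (definitional oracle)
oracle_friedman_chi2 <- function(tab) {
  k <- ncol(tab); N <- nrow(tab)
  ranks <- t(apply(tab, 1, function(row) rank(-row)))
  Rj <- colMeans(ranks)
  12 * N / (k * (k + 1)) * (sum(Rj^2) - k * (k + 1)^2 / 4)
}

# exact one-sided Wilcoxon p by enumerating all 2^K sign assignments of
# the nonzero differences
oracle_wilcoxon_p <- function(diffs) {
  rk <- rank(abs(diffs))
  base <- sum(rk[diffs == 0]) / 2
  r_plus <- sum(rk[diffs > 0]) + base
  r_minus <- sum(rk[diffs < 0]) + base
  T_obs <- min(r_plus, r_minus)
  nz <- rk[diffs != 0]
  K <- length(nz)
  if (K == 0) return(1)
  hits <- 0
  for (mask in 0:(2^K - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(K) - 1)))
    if (base + sum(nz[sel]) <= T_obs + 1e-9) hits <- hits + 1
  }
  hits / 2^K
}

# validity scan used by the chromosome property tests
chromosome_is_valid <- function(chrom) {
  isTRUE(tryCatch(validate_chromosome(chrom), error = function(e) FALSE))
}
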