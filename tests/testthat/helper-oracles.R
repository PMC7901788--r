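# Independent reference implementations used as oracles. Each is written
# from the defining formula, not from the package code paths it checks.

# O(n^2) silhouette from the definition: a = mean intra-cluster distance
# (self excluded), b = min over other clusters of mean distance; singleton
# clusters get 0.
ref_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Exact one-sided Wilcoxon rank-sum p-value by enumerating all
# choose(n1 + n2, n1) group assignments (tie-free inputs).
brute_wrs_p <- function(g1, g2, alternative) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2L, u_of)
  if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
}

# Benjamini-Hochberg step-up from the definition.
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Hypergeometric upper tail P(X >= k) from the choose() formula.
ref_hyper_tail <- function(N, K, n, k) {
  if (k <= max(0, n - (N - K))) return(1)
  kk <- k:min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# mHG statistic of one binary vector via the reference tail.
ref_mhg <- function(v) {
  N <- length(v); K <- sum(v)
  min(vapply(seq_len(N), function(n)
    ref_hyper_tail(N, K, n, sum(v[seq_len(n)])), numeric(1)))
}

# All binary vectors of length N with K ones (columns of combn give the
# positions of the ones).
all_arrangements <- function(N, K) {
  if (K == 0L) return(matrix(0L, 1L, N))
  pos <- utils::combn(N, K)
  t(apply(pos, 2L, function(p) { v <- integer(N); v[p] <- 1L; v }))
}

# Small labelled matrix for io tests.
tiny_matrix <- function() {
  matrix(c(1, 2, 3, 4), 2, 2,
         dimnames = list(c("mirA", "mirB"), c("s1", "s2")))
}

# Random partially-missing cohort list for merge property tests.
random_cohorts <- function(n_batches, universe, seed) {
  set.seed(seed)
  cohorts <- list()
  for (b in seq_len(n_batches)) {
    rows <- sort(sample(universe, sample(2:length(universe), 1L)))
    ncol <- sample(2:4, 1L)
    m <- matrix(rnorm(length(rows) * ncol), length(rows), ncol,
                dimnames = list(rows, sprintf("b%d_s%d", b, seq_len(ncol))))
    cohorts[[sprintf("batch%d", b)]] <- m
  }
  cohorts
}
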