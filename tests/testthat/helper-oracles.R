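# Independent oracles used to verify the package's statistics.  Each is a
# direct transcription of the defining formula or an exhaustive enumeration,
# and never calls the code path it checks.

# Benjamini-Hochberg step-up, straight from the definition:
# sort ascending, q_i = min_{j >= i} m * p_(j) / j, cap at 1, map back.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric P by exhaustive enumeration of every possible
# draw of set B from the universe (set A fixed as the first n_a elements).
hyper_enum_oracle <- function(n_universe, n_a, n_b, k_observed) {
  draws <- utils::combn(n_universe, n_b)
  overlaps <- colSums(draws <= n_a)
  mean(overlaps >= k_observed)
}

# Exact two-sided one-sample Wilcoxon signed-rank P by enumeration of all
# 2^n sign assignments (zero differences removed beforehand; no ties in
# |d| assumed).
signed_rank_enum_oracle <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Pearson chi-squared statistic from Sum (O - E)^2 / E, optional Yates.
pearson_stat_oracle <- function(m, yates = FALSE) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - e)
  if (yates) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / e)
}

# A tiny deterministic DE table for I/O and classification tests.
tiny_de <- function() {
  de_table(gene = c("Ccna2", "Meiosin", "Sycp3", "Gapdh", "Rec8"),
           log2fc = c(-1.2, 2.0, 0.5, 0.0, -0.05),
           padj = c(0.001, 0.02, 0.01, 0.9, 0.01),
           base_mean = c(100, 50, 80, 1000, 30))
}
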