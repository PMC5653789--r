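# Independent oracles and small fixture builders shared across tests.

# Upper-tail hypergeometric probability by exhaustive subset enumeration:
# draw every size-n subset of a universe whose first K elements are marked
# and count those containing at least k marked elements. Deliberately
# brute-force and independent of the implementation under test.
hyper_upper_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Direct quadratic-time BH step-up: q_(i) = min_{j >= i} p_(j) * m / j,
# capped at 1, mapped back to input order.
bh_quadratic <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Spearman rho straight from the mid-rank definition:
# covariance of mid-ranks over the product of their standard deviations.
spearman_midrank_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
}

# Tiny expression matrix with explicit values (genes x samples), half
# control / half case in column order.
tiny_matrix <- function(values, genes = sprintf("g%d", seq_len(nrow(values)))) {
  n <- ncol(values)
  stopifnot(n %% 2 == 0)
  colnames(values) <- sprintf("s%d", seq_len(n))
  rownames(values) <- genes
  groups <- stats::setNames(rep(c("control", "case"), each = n / 2),
                            colnames(values))
  expression_matrix(values, groups)
}

# Null study config: no planted shared effects, no background effects.
null_config <- function(seed, ...)
  sim_config(shared_effect_lfc = 0, background_de_rate = 0, seed = seed, ...)
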