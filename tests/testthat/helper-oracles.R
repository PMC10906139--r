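# Independent brute-force oracles used across tests. These deliberately take
# different code paths from the package implementations they check.

# exact rank-sum p-value by enumerating every group assignment of the
# combined sample (statistic: sum of ranks of the first group)
oracle_rank_sum <- function(x, y, alternative) {
  comb <- c(x, y)
  n1 <- length(x)
  r <- rank(comb)
  W_obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(comb), n1)
  Ws <- apply(idx, 2, function(ii) sum(r[ii]))
  p_ge <- mean(Ws >= W_obs - 1e-9)
  p_le <- mean(Ws <= W_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# exact signed-rank p-value by enumerating all sign flips of the nonzero
# paired differences
oracle_signed_rank <- function(x, y, alternative) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- vapply(seq_len(2^n) - 1L, function(bits) {
    keep <- bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0
    sum(r[keep])
  }, 0)
  p_ge <- mean(Ws >= W_obs - 1e-9)
  p_le <- mean(Ws <= W_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# AUC as the Mann-Whitney pairwise concordance fraction (tie-free scores)
oracle_auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">"))
}

# Lin concordance from explicit population moments
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n; sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}
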