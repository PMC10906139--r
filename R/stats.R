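#' Exact and approximate Wilcoxon tests
#'
#' Rank-based two-group and paired comparisons as used for the subgroup and
#' scenario analyses. For small samples (combined n of at most 12, or at
#' most 12 nonzero paired differences) the p-value is computed by exact
#' enumeration of the permutation distribution of the rank statistic, which
#' remains exact under ties; larger samples use the normal approximation
#' with tie correction (via [stats::wilcox.test()]). Two-sided p-values are
#' twice the smaller tail, capped at 1.
#'
#' @param x,y numeric samples; for the signed-rank test, paired vectors of
#'   equal length (zero differences are dropped).
#' @param alternative \code{"two_sided"} (default), \code{"greater"} (x
#'   tends larger than y), or \code{"less"}.
#' @return List with \code{statistic} (rank-sum of \code{x}, or the positive
#'   signed-rank sum), \code{p_value}, and \code{method}.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 1/choose(6,3)
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if(length(x) == 0L || length(y) == 0L, "both groups must be nonempty")
  stop_if(any(!is.finite(x)) || any(!is.finite(y)), "inputs must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n <= 12L) {
    combs <- combn(n, n1)
    Wdist <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    p_ge <- mean(Wdist >= W - eps)
    p_le <- mean(Wdist <= W + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact permutation enumeration"
  } else {
    alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, method = method)
}

#' @rdname wilcoxon_rank_sum
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if(length(x) != length(y), "paired samples must have equal length")
  stop_if(length(x) == 0L, "samples must be nonempty")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, p_value = 1,
                method = "degenerate: all paired differences zero"))
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- as.vector(signs %*% r)
    eps <- 1e-9
    p_ge <- mean(Wdist >= W - eps)
    p_le <- mean(Wdist <= W + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact sign-enumeration"
  } else {
    alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
    p <- suppressWarnings(
      stats::wilcox.test(d, alternative = alt, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  list(statistic = W, p_value = p, method = method)
}
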