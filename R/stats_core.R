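# Small-sample statistics used throughout the pipeline. Standard procedures
# are delegated to stats::; the exact-permutation Mann-Whitney branch is
# implemented here because the permutation enumeration must handle ties.

new_test_result <- function(statistic, p_value, method) {
  list(statistic = unname(statistic), p_value = min(1, max(0, unname(p_value))),
       method = method)
}

#' Two-sided Mann-Whitney U test
#'
#' For small samples (`n1 + n2 <= exact_limit`) the p-value is computed by
#' exact enumeration of all `choose(n1+n2, n1)` group labelings of the pooled
#' values (valid under ties), as `min(1, 2*min(P(U <= u), P(U >= u)))`. Larger
#' samples use the normal approximation with midrank tie correction and
#' continuity correction. The statistic is U for `x`.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return A list with `statistic`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 14L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  u_obs <- u_of(seq_len(n1))
  if (n1 + n2 <= exact_limit) {
    labelings <- utils::combn(n1 + n2, n1)
    us <- apply(labelings, 2L, u_of)
    p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    new_test_result(u_obs, p, "exact")
  } else {
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    new_test_result(u_obs, w$p.value, "normal_approx")
  }
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood ("small-p") two-sided p-value: the sum of P(k | n, p0)
#' over all k whose point probability does not exceed that of the observed
#' count. `n = 0` returns p = 1.
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @export
binomial_two_sided <- function(x, n, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (x < 0 || x > n) stop("require 0 <= x <= n")
  if (n == 0L) return(new_test_result(NA_real_, 1, "exact"))
  bt <- stats::binom.test(x, n, p0)
  new_test_result(x / n, bt$p.value, "exact")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's. A table with a
#' zero margin is degenerate and returns p = 1.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(new_test_result(NA_real_, 1, "exact"))
  ft <- stats::fisher.test(tab)
  new_test_result(unname(ft$estimate), ft$p.value, "exact")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
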