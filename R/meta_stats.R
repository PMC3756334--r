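#' Exact binomial test
#'
#' One-sided p is the upper tail `P(X >= k)` under `Binomial(n, p0)`;
#' two-sided sums all outcomes with point probability at or below that of
#' `k` (delegated to [stats::binom.test()], which uses exactly this
#' definition).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials (positive).
#' @param p0 null success probability in (0, 1).
#' @param sided `"two"` or `"one"`.
#' @return p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.5, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n < 1L) stop("n must be positive")
  if (k < 0L || k > n) stop("k must lie in 0..n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (sided == "one")
    stats::binom.test(k, n, p0, alternative = "greater")$p.value
  else
    stats::binom.test(k, n, p0, alternative = "two.sided")$p.value
}

#' Log-likelihood-ratio (G) test on a 2x2 table
#'
#' `G = 2 * sum(O * ln(O / E))` with expected counts from independence of
#' the margins, compared against chi-square with 1 degree of freedom.
#' Invariant to swapping both rows and both columns.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return list with `G`, `p_value`, `df` and the expected table.
#' @export
g_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("g_test needs a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  terms <- ifelse(table == 0, 0, table * log(table / E))
  G <- 2 * sum(terms)
  list(G = G, p_value = stats::pchisq(G, df = 1, lower.tail = FALSE),
       df = 1L, expected = E)
}

#' Dataset-level jackknife of the pooled node-recovery comparison
#'
#' Each matrix is included with probability `inclusion_p` in each of
#' `n_resamples` resamples; the pooled node-recovery rank test is
#' recomputed on every included subset. Resamples that include no matrix
#' are redrawn (and counted).
#'
#' @param results list of `node_recovery_result` objects of one mode.
#' @param n_resamples number of resamples (50 at full scale).
#' @param inclusion_p per-matrix inclusion probability (0.5).
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list with per-resample p-values, the count significant at
#'   `alpha`, and the number of redraws.
#' @export
dataset_jackknife <- function(results, n_resamples = 50L, inclusion_p = 0.5,
                              alpha = 0.05, seed = 1L) {
  results <- Filter(function(r) !isTRUE(r$undefined), results)
  nm <- length(results)
  if (nm == 0L) stop("no results to resample")
  ps <- numeric(n_resamples)
  redraws <- 0L
  for (i in seq_len(n_resamples)) {
    set.seed(derive_seed(seed, "jack", i))
    repeat {
      inc <- stats::runif(nm) < inclusion_p
      if (any(inc)) break
      redraws <- redraws + 1L
    }
    ps[i] <- aggregate_node_recovery(results[inc])$p_value
  }
  list(p_values = ps,
       n_significant = sum(ps < alpha),
       n_resamples = n_resamples,
       inclusion_p = inclusion_p,
       redraws = redraws)
}
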