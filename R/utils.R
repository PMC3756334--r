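#' Derive a reproducible sub-seed
#'
#' Hashes a master seed together with any number of identifying labels
#' (matrix id, taxon, replicate index, stage name) into an integer seed
#' below 2^31, so that every unit of stochastic work draws from its own
#' deterministic stream and results are independent of execution order.
#'
#' @param seed master integer seed.
#' @param ... further identifiers (coerced to character).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483629
  as.integer(h + 1)
}

#' Rank-based permutation p-value
#'
#' The `(r + 1) / (n + 1)` convention with ties counted in `r`: for the
#' low tail, `r` is the number of null values at or below the observed
#' value. With 0 of 500 null replicates below the observed value this
#' gives 1/501 (about 0.002), with 259 of 500 it gives 260/501 (about
#' 0.52).
#'
#' @param null numeric vector of null-replicate statistics.
#' @param observed observed statistic.
#' @param tail `"low"` (observed significantly small) or `"high"`.
#' @return p-value in (0, 1].
#' @export
rank_p <- function(null, observed, tail = c("low", "high")) {
  tail <- match.arg(tail)
  r <- if (tail == "low") sum(null <= observed) else sum(null >= observed)
  (r + 1) / (length(null) + 1)
}
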