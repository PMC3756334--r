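#' Root-distance shift of one pseudofossilized taxon
#'
#' Stage 2 of the pseudoextinction protocol. The taxon's mean distance to
#' the root over all MPTs is computed on the intact matrix (`d_orig`),
#' after replacing its scored soft cells with MISSING (`d_foss`), and
#' after each of `n_reps` matched random degradations in which the same
#' number of its scored cells (drawn across both partitions) are
#' blanked. `delta = d_foss - d_orig`; negative means the taxon moved
#' toward the root (stemward, "down"). The magnitude of `delta` is ranked
#' against the magnitudes of the null deltas, giving a two-sided-in-
#' direction permutation p. All searches keep fully resolved MPTs.
#'
#' A taxon with no scored soft cells cannot be perturbed: its delta is 0
#' and it is flagged `unperturbable`. The outgroup is never fossilized.
#'
#' @param m a curated `char_matrix`.
#' @param taxon taxon label (not the outgroup).
#' @param n_reps matched random replicates (500 at full scale).
#' @param metric `"nodes"` (internal nodes to root) or `"patristic"`
#'   (ACCTRAN parsimony steps to root).
#' @param settings a [search_settings()] profile.
#' @param seed master seed.
#' @param orig optional precomputed full-matrix `tree_set`, shared across
#'   the taxa of one matrix (must carry trees when `metric = "patristic"`).
#' @return a `taxon_shift_result`.
#' @export
run_taxon_shift <- function(m, taxon, n_reps = 500L,
                            metric = c("nodes", "patristic"),
                            settings = desk_settings(), seed = 1L,
                            orig = NULL) {
  metric <- match.arg(metric)
  n_reps <- as.integer(n_reps)
  if (taxon == m$outgroup) stop("the outgroup is never fossilized")
  if (!taxon %in% taxa_of(m)) stop("taxon '", taxon, "' not in matrix")
  need_trees <- metric == "patristic"
  if (is.null(orig))
    orig <- heuristic_search(m, settings, seed = derive_seed(seed, "orig"),
                             return_trees = need_trees)
  dist_of <- function(ts, mi) {
    if (metric == "nodes") mean_root_distance(ts, taxon)
    else mean_root_distance(ts, taxon, "patristic", mi)
  }
  d_orig <- dist_of(orig, m)
  k <- fossilizable_count(m, taxon)
  if (k == 0L) {
    return(structure(list(
      taxon = taxon, metric = metric, k_deleted = 0L,
      d_orig = d_orig, d_foss = d_orig, delta = 0,
      null_deltas = rep(0, n_reps), p_magnitude = 1,
      direction = "none", unperturbable = TRUE, n_reps = n_reps,
      seed = seed), class = "taxon_shift_result"))
  }
  mf <- fossilize_taxon(m, taxon)
  tsf <- heuristic_search(mf, settings, seed = derive_seed(seed, taxon, "foss"),
                          return_trees = need_trees)
  d_foss <- dist_of(tsf, mf)
  delta <- d_foss - d_orig
  null_deltas <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(derive_seed(seed, taxon, "blank", i))
    mi <- randomize_taxon(m, taxon, k)
    tsi <- heuristic_search(mi, settings,
                            seed = derive_seed(seed, taxon, "nullsearch", i),
                            return_trees = need_trees)
    null_deltas[i] <- dist_of(tsi, mi) - d_orig
  }
  structure(list(
    taxon = taxon, metric = metric, k_deleted = k,
    d_orig = d_orig, d_foss = d_foss, delta = delta,
    null_deltas = null_deltas,
    p_magnitude = rank_p(abs(null_deltas), abs(delta), "high"),
    direction = shift_direction(delta),
    unperturbable = FALSE, n_reps = n_reps,
    seed = seed), class = "taxon_shift_result")
}

# movement tolerance absorbing float noise in means over MPTs
.shift_tol <- 1e-9

shift_direction <- function(delta, tol = .shift_tol) {
  if (abs(delta) <= tol) "none" else if (delta < 0) "down" else "up"
}

#' @export
print.taxon_shift_result <- function(x, ...) {
  cat(sprintf(
    "taxon shift '%s' (%s): %.3f -> %.3f (delta %+0.3f, %s), p = %.4g%s\n",
    x$taxon, x$metric, x$d_orig, x$d_foss, x$delta, x$direction,
    x$p_magnitude, if (isTRUE(x$unperturbable)) " [unperturbable]" else ""))
  invisible(x)
}

#' Classify the direction and significance of a taxon shift
#'
#' Direction follows the sign of delta (zero deltas are `"none"`
#' regardless of p); significance compares the shift magnitude with the
#' matched random-null magnitudes at level `alpha`.
#'
#' @param result a `taxon_shift_result`.
#' @param alpha significance level (0.05, the 5% tail).
#' @return list with `direction` and `significant`.
#' @export
classify_shift <- function(result, alpha = 0.05) {
  dir <- shift_direction(result$delta)
  list(direction = dir,
       significant = dir != "none" && result$p_magnitude <= alpha)
}

#' Taxon shift test for every taxon of a matrix
#'
#' Runs [run_taxon_shift()] for each non-outgroup taxon, sharing one
#' full-matrix search.
#'
#' @inheritParams run_taxon_shift
#' @param taxa subset of taxa to perturb (default: all but the outgroup).
#' @return list of `taxon_shift_result` objects, named by taxon.
#' @export
run_taxon_shift_all <- function(m, n_reps = 500L,
                                metric = c("nodes", "patristic"),
                                settings = desk_settings(), seed = 1L,
                                taxa = NULL) {
  metric <- match.arg(metric)
  if (is.null(taxa)) taxa <- setdiff(taxa_of(m), m$outgroup)
  orig <- heuristic_search(m, settings, seed = derive_seed(seed, "orig"),
                           return_trees = metric == "patristic")
  out <- lapply(taxa, function(tx)
    run_taxon_shift(m, tx, n_reps = n_reps, metric = metric,
                    settings = settings, seed = derive_seed(seed, tx),
                    orig = orig))
  stats::setNames(out, taxa)
}

#' Pooled counts of taxon movement and significance
#'
#' For the `"fossilization"` condition each taxon contributes its own
#' shift. For the `"random"` condition the default `"matched"`
#' accounting takes each taxon's first random replicate as the matched
#' random observation (one draw per taxon, the same design size as the
#' fossilization condition); `"all_replicates"` pools the direction of
#' every null replicate of every taxon. Counts are pooled over taxa and
#' datasets (summed, not averaged per dataset).
#'
#' @param results list of `taxon_shift_result` (possibly across datasets).
#' @param condition `"fossilization"` or `"random"`.
#' @param alpha significance level for the shift magnitudes.
#' @param accounting random-condition accounting (see above).
#' @return a list of pooled counts: `n`, `moved`, `moved_down`,
#'   `moved_up`, and for the fossilization condition `significant`,
#'   `significant_down`, `significant_up`.
#' @export
summarize_shifts <- function(results,
                             condition = c("fossilization", "random"),
                             alpha = 0.05,
                             accounting = c("matched", "all_replicates")) {
  condition <- match.arg(condition)
  accounting <- match.arg(accounting)
  if (condition == "fossilization") {
    deltas <- vapply(results, function(r) r$delta, 0)
    dirs <- vapply(deltas, shift_direction, "")
    sig <- vapply(results, function(r) classify_shift(r, alpha)$significant, TRUE)
    list(condition = condition,
         n = length(results),
         moved = sum(dirs != "none"),
         moved_down = sum(dirs == "down"),
         moved_up = sum(dirs == "up"),
         significant = sum(sig),
         significant_down = sum(sig & dirs == "down"),
         significant_up = sum(sig & dirs == "up"))
  } else {
    deltas <- if (accounting == "matched")
      vapply(results, function(r) r$null_deltas[1L], 0)
    else unlist(lapply(results, function(r) r$null_deltas))
    dirs <- vapply(deltas, shift_direction, "")
    list(condition = condition,
         accounting = accounting,
         n = length(deltas),
         moved = sum(dirs != "none"),
         moved_down = sum(dirs == "down"),
         moved_up = sum(dirs == "up"))
  }
}
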