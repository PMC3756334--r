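#' Search settings for parsimony analyses
#'
#' @param n_addition_replicates random-addition-sequence starts per search.
#' @param hold_per_replicate cap on equally parsimonious trees collected
#'   around each replicate's optimum.
#' @param max_trees cap on the total number of most parsimonious trees held.
#' @param swap branch-swapping neighbourhood, `"spr"` or `"tbr"`.
#' @param plateau_budget cap on tree-length evaluations spent swapping
#'   through the plateau of equally parsimonious trees (`Inf` = none).
#' @param branch_collapsing `"none"` keeps all MPTs fully resolved (zero
#'   length branches retained), as the node-counting metrics require.
#' @param rng_seed integer seed recorded in every tree set produced.
#' @return a `search_settings` list.
#' @export
search_settings <- function(n_addition_replicates = 100L,
                            hold_per_replicate = 1000L,
                            max_trees = 10000L,
                            swap = c("tbr", "spr"),
                            plateau_budget = Inf,
                            branch_collapsing = "none",
                            rng_seed = 1L) {
  swap <- match.arg(swap)
  stopifnot(n_addition_replicates >= 1L, hold_per_replicate >= 1L,
            max_trees >= 1L, plateau_budget > 0)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 hold_per_replicate = as.integer(hold_per_replicate),
                 max_trees = as.integer(max_trees),
                 swap = swap,
                 plateau_budget = plateau_budget,
                 branch_collapsing = branch_collapsing,
                 rng_seed = as.integer(rng_seed)),
            class = "search_settings")
}

#' Desk-scale search profile
#'
#' Reduced search effort for simulation studies on small synthetic
#' matrices: 5 random-addition starts with SPR swapping and bounded
#' plateau exploration. Scores on matrices of this size match exhaustive
#' search (see the package tests); the reduced effort changes runtime,
#' not the statistical logic.
#' @return a `search_settings` list.
#' @export
desk_settings <- function() {
  search_settings(n_addition_replicates = 5L, hold_per_replicate = 500L,
                  max_trees = 200L, swap = "spr", plateau_budget = 5e4)
}

#' Full-scale search profile
#'
#' 100 random additions with TBR swapping, holding up to 1000 trees per
#' replicate and 10000 trees overall, no branch collapsing.
#' @return a `search_settings` list.
#' @export
full_settings <- function() {
  search_settings(n_addition_replicates = 100L, hold_per_replicate = 1000L,
                  max_trees = 10000L, swap = "tbr", plateau_budget = Inf)
}

engine_cells <- function(m, taxa = taxa_of(m)) {
  cells <- m$cells[taxa, , drop = FALSE]
  storage.mode(cells) <- "integer"
  cells
}

edge_to_phylo <- function(edge, tip_labels) {
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, tip.label = tip_labels,
                 Nnode = length(tip_labels) - 1L),
            class = "phylo", order = "cladewise")
}

wrap_tree_set <- function(res, m, settings, seed) {
  taxa <- taxa_of(m)
  trees <- NULL
  if (!is.null(res$trees)) {
    trees <- lapply(res$trees, edge_to_phylo, tip_labels = taxa)
    class(trees) <- "multiPhylo"
  }
  structure(list(
    score = res$score,
    n_trees = res$n_trees,
    trees = trees,
    mean_root_distance = stats::setNames(res$mean_root_distance, taxa),
    common_clades = res$common_clades,
    taxa = taxa,
    outgroup = m$outgroup,
    settings = settings,
    seed = seed,
    hit_tree_cap = res$hit_tree_cap,
    hit_eval_cap = res$hit_eval_cap,
    n_topologies = res$n_topologies), class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d MPTs at %d steps over %d taxa (outgroup '%s')%s\n",
              x$n_trees, x$score, length(x$taxa), x$outgroup,
              if (isTRUE(x$hit_tree_cap) || isTRUE(x$hit_eval_cap))
                " [tree/eval cap hit]" else ""))
  invisible(x)
}

#' Parsimony length of a tree
#'
#' Minimum number of character-state changes of `tree` on `m`, summed
#' over characters: Fitch optimization for unordered characters, Farris
#' interval (Wagner) counting for ordered ones. Missing cells act as the
#' full state set. Exact for binary trees; invariant under re-rooting.
#'
#' @param tree an `ape::phylo` whose tips are taxa of `m`.
#' @param m a `char_matrix`.
#' @return integer step count.
#' @export
fitch_length <- function(tree, m) {
  if (!all(tree$tip.label %in% taxa_of(m)))
    stop("tree tip '", setdiff(tree$tip.label, taxa_of(m))[1L],
         "' absent from matrix")
  cells <- engine_cells(m, tree$tip.label)
  tree_length_cpp(tree$edge, length(tree$tip.label), cells,
                  m$ordering == "ordered")
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence stepwise addition followed by SPR or TBR
#' branch swapping; all distinct optimal trees encountered are collected
#' by swapping through the plateau of equally parsimonious trees (up to
#' `max_trees`). Trees are rooted on the matrix outgroup and kept fully
#' resolved (no branch collapsing). Reproducible given `seed`.
#'
#' @param m a curated `char_matrix` with at least 4 taxa.
#' @param settings a [search_settings()] object.
#' @param seed integer RNG seed (defaults to the settings seed).
#' @param return_trees keep the MPTs as `ape::phylo` objects (the clade
#'   and root-distance summaries are always available without them).
#' @return a `tree_set`: MPT summaries (`score`, `n_trees`,
#'   `mean_root_distance` per taxon, `common_clades`) and optionally the
#'   trees themselves.
#' @export
heuristic_search <- function(m, settings = desk_settings(),
                             seed = settings$rng_seed, return_trees = FALSE) {
  if (n_taxa(m) < 4L) stop("heuristic search requires at least 4 taxa")
  if (n_char(m) < 1L) stop("matrix has no characters")
  og <- match(m$outgroup, taxa_of(m)) - 1L
  budget <- if (is.finite(settings$plateau_budget)) settings$plateau_budget else 0
  res <- heuristic_search_cpp(engine_cells(m), m$ordering == "ordered", og,
                              settings$n_addition_replicates, settings$swap,
                              settings$hold_per_replicate, settings$max_trees,
                              budget, as.integer(seed), return_trees)
  res$n_topologies <- NA_real_
  wrap_tree_set(res, m, settings, seed)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all unrooted binary topologies (at most 9 taxa) and returns
#' every minimum-length tree, rooted on the outgroup. Serves as the exact
#' oracle against which the heuristic search is validated.
#'
#' @param m a `char_matrix` with 4--9 taxa.
#' @param return_trees keep the MPTs as `ape::phylo` objects.
#' @return a `tree_set` with `n_topologies` recording the number of
#'   topologies enumerated.
#' @export
exhaustive_search <- function(m, return_trees = TRUE) {
  if (n_taxa(m) < 4L) stop("exhaustive search requires at least 4 taxa")
  if (n_taxa(m) > 9L) stop("exhaustive search is limited to 9 taxa")
  og <- match(m$outgroup, taxa_of(m)) - 1L
  res <- exhaustive_search_cpp(engine_cells(m), m$ordering == "ordered", og,
                               return_trees)
  wrap_tree_set(res, m, search_settings(rng_seed = 0L), 0L)
}

#' Non-trivial rooted clades of a tree
#'
#' @param tree a rooted `ape::phylo`.
#' @return character vector of clade keys (sorted tip labels joined with
#'   `"|"`), excluding singletons and the full leaf set.
#' @export
clade_set <- function(tree) {
  ntip <- length(tree$tip.label)
  hex <- tree_clades_cpp(tree$edge, ntip)
  keys <- vapply(hex, function(h) {
    tips <- mask_tips(h, ntip)
    if (length(tips) < 2L || length(tips) >= ntip) return(NA_character_)
    paste(sort(tree$tip.label[tips]), collapse = "|")
  }, "", USE.NAMES = FALSE)
  unique(keys[!is.na(keys)])
}

# decode a 64-bit hex leaf mask into 1-based tip indices
mask_tips <- function(hex, ntip) {
  lo <- strtoi(substr(hex, 9, 16), 16L)
  hi <- strtoi(substr(hex, 1, 8), 16L)
  bits <- c(bitwAnd(bitwShiftR(lo, 0:31), 1L), bitwAnd(bitwShiftR(hi, 0:31), 1L))
  which(bits[seq_len(ntip)] == 1L)
}

#' Strict consensus of a set of trees
#'
#' The rooted tree containing exactly the clades present in every member.
#'
#' @param x a `tree_set` (searched with `return_trees = TRUE`) or an
#'   `ape::multiPhylo`.
#' @return an `ape::phylo`.
#' @export
strict_consensus <- function(x) {
  trees <- if (inherits(x, "tree_set")) x$trees else x
  if (is.null(trees) || length(trees) == 0L)
    stop("no trees to form a consensus (search with return_trees = TRUE)")
  if (inherits(trees, "phylo")) return(trees)
  if (length(trees) == 1L) return(trees[[1L]])
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Node recovery index between two trees
#'
#' Fraction of the benchmark tree's non-trivial clades present in the
#' test tree; both trees must carry identical leaf sets (character
#' deletion perturbs signal, never taxa).
#'
#' @param benchmark,test rooted `ape::phylo` trees.
#' @return value in \[0, 1\]; `NaN` (flagged undefined) when the
#'   benchmark has no non-trivial clades.
#' @export
node_recovery_index <- function(benchmark, test) {
  if (!setequal(benchmark$tip.label, test$tip.label))
    stop("benchmark and test trees have different leaf sets")
  b <- clade_set(benchmark)
  if (length(b) == 0L) return(NaN)
  length(intersect(b, clade_set(test))) / length(b)
}

# edges on the path tip -> root; returns edge row indices
root_path_edges <- function(tree, tip_index) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  eidx <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  eidx[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  path <- integer(0)
  v <- tip_index
  while (v != root) {
    path <- c(path, eidx[v])
    v <- parent[v]
  }
  path
}

#' Mean distance of a taxon from the root over a tree set
#'
#' The `nodes` metric counts internal nodes strictly between the terminal
#' and the root (both endpoints excluded), averaged over all MPTs; a leaf
#' attached directly to the root scores 0. The `patristic` metric sums
#' per-edge parsimony steps along the terminal-to-root path, with
#' ambiguous change placements resolved by ACCTRAN, and requires both the
#' trees and the data matrix.
#'
#' @param x a `tree_set`, `multiPhylo` or single `phylo`.
#' @param taxon taxon label (must be in every tree).
#' @param metric `"nodes"` or `"patristic"`.
#' @param m the `char_matrix` (patristic metric only).
#' @return mean distance, a non-negative number.
#' @export
mean_root_distance <- function(x, taxon, metric = c("nodes", "patristic"),
                               m = NULL) {
  metric <- match.arg(metric)
  if (inherits(x, "tree_set") && metric == "nodes") {
    d <- x$mean_root_distance[taxon]
    if (is.na(d)) stop("taxon '", taxon, "' not in tree set")
    return(unname(d))
  }
  trees <- if (inherits(x, "tree_set")) x$trees else x
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(trees) || length(trees) == 0L)
    stop("no trees available (search with return_trees = TRUE)")
  vals <- vapply(trees, function(tr) {
    ti <- match(taxon, tr$tip.label)
    if (is.na(ti)) stop("taxon '", taxon, "' missing from a tree")
    path <- root_path_edges(tr, ti)
    if (metric == "nodes") {
      length(path) - 1L
    } else {
      if (is.null(m)) stop("patristic metric requires the data matrix")
      wt <- acctran_tree(tr, m)
      sum(wt$edge.length[path])
    }
  }, 0)
  mean(vals)
}

# per-edge parsimony changes under a rooted ACCTRAN resolution; the root
# state is resolved toward the outgroup so stem-edge changes stay on the
# terminal-to-root paths of the ingroup
acctran_tree <- function(tree, m) {
  og <- match(m$outgroup, tree$tip.label)
  if (is.na(og)) og <- 1L
  tree$edge.length <- acctran_lengths_cpp(tree$edge, length(tree$tip.label),
                                          engine_cells(m, tree$tip.label),
                                          m$ordering == "ordered", og)
  tree
}
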