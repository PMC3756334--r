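#' Specification for a synthetic partitioned matrix
#'
#' Describes one simulated dataset emulating a compiled morphological
#' matrix: a Yule (pure-birth, unit rate) ingroup topology with an
#' all-plesiomorphic outgroup attached at the root, binary characters
#' (multistate optional) split into hard and soft partitions, and a
#' signal mode. Character changes always cover the internal ingroup
#' edges uniformly (soft anatomy informs every depth of the tree, as it
#' does in real matrices); the signal mode decides which tissue type
#' owns each change. Under `"exchangeable"` ownership ignores depth, so
#' the hard/soft labels are statistically interchangeable (the null
#' condition). Under `"decay_biased"` synapomorphies in the crownmost
#' depth tercile are soft-owned with probability `crown_bias` and those
#' in the rootmost tercile hard-owned with probability `hard_root_bias`
#' (mid-zone changes split evenly), emulating the decay ordering in
#' which the derived synapomorphies diagnosing recent divergences
#' reside in soft tissue while biomineralized characters redundantly
#' diagnose the deep divergences.
#'
#' @param n_taxa ingroup taxa (the outgroup is added on top).
#' @param n_hard,n_soft characters per partition.
#' @param n_states number of states (2 = binary, the default).
#' @param signal_mode `"exchangeable"` or `"decay_biased"`.
#' @param homoplasy_rate per-character probability of one extra
#'   convergent/reversal change on a uniformly chosen ingroup edge.
#' @param crown_bias probability that a crown-zone change is soft-owned
#'   (decay-biased mode).
#' @param hard_root_bias probability that a root-zone change is
#'   hard-owned (decay-biased mode).
#' @param missing_rate per-partition probability that an ingroup cell is
#'   missing.
#' @param outgroup_label label of the added outgroup taxon.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_taxa = 15L, n_hard = 30L, n_soft = 30L,
                           n_states = 2L,
                           signal_mode = c("exchangeable", "decay_biased"),
                           homoplasy_rate = 0.5, crown_bias = 0.8,
                           hard_root_bias = 0.6, missing_rate = 0.10,
                           outgroup_label = "OUT", seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_taxa >= 5L, n_hard + n_soft >= 1L, n_states >= 2L,
            homoplasy_rate >= 0, homoplasy_rate <= 1,
            crown_bias >= 0, crown_bias <= 1,
            hard_root_bias >= 0, hard_root_bias <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_taxa = as.integer(n_taxa), n_hard = as.integer(n_hard),
                 n_soft = as.integer(n_soft), n_states = as.integer(n_states),
                 signal_mode = signal_mode, homoplasy_rate = homoplasy_rate,
                 crown_bias = crown_bias, hard_root_bias = hard_root_bias,
                 missing_rate = missing_rate, outgroup_label = outgroup_label,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

#' Simulate the generating tree
#'
#' A Yule topology conditioned on `n_taxa` ingroup tips (via
#' `ape::rphylo` with unit birth and zero death), with the outgroup
#' attached at the root so that the basal node of every inferred tree has
#' a true counterpart.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (defaults to the spec seed).
#' @return a rooted binary `ape::phylo` with `n_taxa + 1` tips.
#' @export
generate_tree <- function(spec, seed = spec$seed) {
  set.seed(seed)
  ing <- ape::rphylo(spec$n_taxa, birth = 1, death = 0)
  nwk <- sub(";\\s*$", "", ape::write.tree(ing))
  ape::read.tree(text = paste0("(", spec$outgroup_label, ":1,", nwk, ":1);"))
}

# internal ingroup edges eligible to carry a primary change: the derived
# clade must hold 2..(n_taxa - 1) ingroup tips so the character can be
# parsimony-informative
candidate_edges <- function(tree, outgroup) {
  ntip <- length(tree$tip.label)
  og <- match(outgroup, tree$tip.label)
  nn <- max(tree$edge)
  kids_tips <- vector("list", nn)
  for (i in seq_len(ntip)) kids_tips[[i]] <- i
  # postorder accumulation
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    kids_tips[[p]] <- c(kids_tips[[p]], kids_tips[[ch]])
  }
  depth <- integer(nn)
  root <- ntip + 1L
  for (e in seq_len(nrow(tree$edge)))
    depth[tree$edge[e, 2L]] <- depth[tree$edge[e, 1L]] + 1L
  sizes <- vapply(kids_tips, length, 0L)
  has_og <- vapply(kids_tips, function(v) og %in% v, TRUE)
  child <- tree$edge[, 2L]
  ok <- !has_og[child] & sizes[child] >= 2L & sizes[child] <= length(tree$tip.label) - 2L
  data.frame(edge = which(ok),
             child = child[ok],
             depth = depth[tree$edge[ok, 1L]],
             size = sizes[child[ok]])
}

# all ingroup edges (pendant included), for homoplasy placement
ingroup_edges <- function(tree, outgroup) {
  ntip <- length(tree$tip.label)
  og <- match(outgroup, tree$tip.label)
  nn <- max(tree$edge)
  kids_tips <- vector("list", nn)
  for (i in seq_len(ntip)) kids_tips[[i]] <- i
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    kids_tips[[p]] <- c(kids_tips[[p]], kids_tips[[ch]])
  }
  child <- tree$edge[, 2L]
  keep <- !vapply(kids_tips[child], function(v) og %in% v, TRUE)
  list(edges = which(keep), tips_below = kids_tips)
}

#' Evolve a partitioned character matrix on a tree
#'
#' Every character receives one primary state change on a uniformly
#' chosen internal ingroup edge, turning the tips of the derived clade
#' to state 1 against an all-0 background (the outgroup stays
#' plesiomorphic); the partition label of each character is then
#' assigned from the change's depth zone per the spec's signal mode.
#' With probability `homoplasy_rate` an
#' extra convergent or reversal change is applied on a uniformly chosen
#' ingroup edge. Missing entries are then injected per partition at
#' `missing_rate` (the outgroup row stays fully scored). The truth
#' record stores the tree and every change placement.
#'
#' @param tree output of [generate_tree()].
#' @param spec the matching [synthetic_spec()].
#' @param seed RNG seed.
#' @return list with `matrix` (a `char_matrix`) and `truth`.
#' @export
evolve_matrix <- function(tree, spec, seed = spec$seed) {
  set.seed(derive_seed(seed, "evolve"))
  ntip <- length(tree$tip.label)
  cand <- candidate_edges(tree, spec$outgroup_label)
  if (nrow(cand) == 0L)
    stop("tree has no internal ingroup edges able to carry informative changes")
  ig <- ingroup_edges(tree, spec$outgroup_label)
  # depth zones (terciles of the root-to-crown depth range)
  terc <- cut(cand$depth, breaks = 3, labels = c("root", "mid", "crown"),
              include.lowest = TRUE)

  nchar_total <- spec$n_hard + spec$n_soft
  # primary changes cover the tree uniformly in both modes; the signal
  # mode decides only which tissue type owns each change. Under decay
  # bias, crown-zone changes are soft-owned with probability crown_bias
  # and root-zone changes hard-owned with probability hard_root_bias
  # (mid-zone changes are split evenly), subject to the requested
  # partition totals.
  partition <- rep(c("hard", "soft"), c(spec$n_hard, spec$n_soft))
  chosen <- integer(nchar_total)
  if (spec$signal_mode == "decay_biased") {
    # Soft anatomy informs every depth of the tree: soft changes are
    # placed uniformly over the candidate edges, so a soft-only matrix
    # resembles a random remainder of the full matrix. Hard changes are
    # rootward-biased: with probability hard_root_bias a hard change
    # goes to the root-zone, otherwise it falls uniformly on edges with
    # the crown zone down-weighted by (1 - crown_bias) -- recent
    # divergences are diagnosed by soft tissue with probability
    # crown_bias, so fossilization (hard-only data) strips the crown.
    root_pool <- which(terc == "root")
    w_avoid <- ifelse(terc == "crown", 1 - spec$crown_bias, 1)
    if (sum(w_avoid) <= 0) w_avoid[] <- 1
    for (cc in seq_len(nchar_total)) {
      if (partition[cc] == "hard") {
        chosen[cc] <- if (stats::runif(1) < spec$hard_root_bias &&
                          length(root_pool) > 0)
          root_pool[sample.int(length(root_pool), 1L)]
        else sample.int(nrow(cand), 1L, prob = w_avoid)
      } else {
        chosen[cc] <- sample.int(nrow(cand), 1L)
      }
    }
  } else {
    chosen <- sample.int(nrow(cand), nchar_total, replace = TRUE)
  }
  zones <- as.character(terc[chosen])
  cells <- matrix(0L, ntip, nchar_total,
                  dimnames = list(tree$tip.label, NULL))
  placements <- vector("list", nchar_total)
  for (cc in seq_len(nchar_total)) {
    e <- cand$edge[chosen[cc]]
    below <- ig$tips_below[[tree$edge[e, 2L]]]
    cells[below, cc] <- 1L
    extra <- integer(0)
    if (stats::runif(1) < spec$homoplasy_rate) {
      e2 <- ig$edges[sample.int(length(ig$edges), 1L)]
      b2 <- ig$tips_below[[tree$edge[e2, 2L]]]
      if (spec$n_states == 2L) {
        cells[b2, cc] <- 1L - cells[b2, cc]
      } else {
        cells[b2, cc] <- sample.int(spec$n_states, 1L) - 1L
      }
      extra <- e2
    }
    placements[[cc]] <- list(primary = e, zone = zones[cc], extra = extra)
  }
  # state integers -> bitmasks, then missing data per partition
  cells[] <- bitwShiftL(1L, cells)
  og_row <- match(spec$outgroup_label, rownames(cells))
  for (p in c("hard", "soft")) {
    cols <- which(partition == p)
    if (length(cols) == 0L || spec$missing_rate == 0) next
    blank <- matrix(stats::runif(ntip * length(cols)) < spec$missing_rate,
                    ntip, length(cols))
    blank[og_row, ] <- FALSE
    cells[, cols][blank] <- NA_integer_
  }
  list(matrix = character_matrix(cells, partition, spec$outgroup_label),
       truth = list(tree = tree, placements = placements, spec = spec,
                    n_changes = sum(vapply(placements, function(p)
                      1L + length(p$extra), 0L))))
}

#' Generate a suite of includable synthetic matrices
#'
#' Draws per-matrix parameters from the given ranges, simulates, curates
#' with the standard pipeline and keeps only matrices passing the
#' inclusion thresholds (re-drawing a fresh seed when one fails, up to
#' `max_tries`). Stands in for a compilation of published matrices.
#'
#' @param n_matrices number of matrices to emit.
#' @param mode `"exchangeable"` or `"decay_biased"` (applied to all).
#' @param n_taxa scalar or range of ingroup taxon counts (default 10--40).
#' @param n_char total characters before curation.
#' @param hard_fraction scalar or range for the hard-character fraction
#'   (default 0.2--0.8).
#' @param seed master seed.
#' @param max_tries redraw attempts per matrix.
#' @param ... further [synthetic_spec()] fields (homoplasy_rate,
#'   crown_bias, missing_rate, ...).
#' @return list with `matrices` (curated `char_matrix` objects, named),
#'   `truths` and `manifest`.
#' @export
make_benchmark_suite <- function(n_matrices, mode = "exchangeable",
                                 n_taxa = c(10L, 40L), n_char = 60L,
                                 hard_fraction = c(0.2, 0.8), seed = 1L,
                                 max_tries = 25L, ...) {
  matrices <- list(); truths <- list(); manifest <- list()
  for (i in seq_len(n_matrices)) {
    id <- sprintf("m%03d", i)
    set.seed(derive_seed(seed, "suite", i))
    nt <- if (length(n_taxa) == 2L) sample(n_taxa[1L]:n_taxa[2L], 1L) else n_taxa
    hf <- if (length(hard_fraction) == 2L)
      stats::runif(1, hard_fraction[1L], hard_fraction[2L]) else hard_fraction
    nh <- as.integer(round(hf * n_char))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      sp <- synthetic_spec(n_taxa = nt, n_hard = nh, n_soft = n_char - nh,
                           signal_mode = mode,
                           seed = derive_seed(seed, "mat", i, try), ...)
      tr <- generate_tree(sp)
      em <- evolve_matrix(tr, sp)
      cur <- curate_matrix(em$matrix)
      if (cur$inclusion$include) {
        matrices[[id]] <- cur$matrix
        truths[[id]] <- em$truth
        manifest[[id]] <- list(spec = sp, tries = try,
                               inclusion = cur$inclusion)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to generate an includable matrix for ", id,
                  " after ", max_tries, " tries")
  }
  list(matrices = matrices, truths = truths, manifest = manifest,
       mode = mode, seed = seed)
}
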