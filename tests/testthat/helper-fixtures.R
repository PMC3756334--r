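# Fixture builders and independent oracles used across the tests.
# The string parser and clade enumeration here are deliberately written
# independently of the package internals.

# parse "10?{02}" into a bitmask row (NA = missing)
parse_row <- function(s) {
  out <- integer(0)
  chars <- strsplit(s, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "?" || ch == "-") { out <- c(out, NA_integer_); i <- i + 1 }
    else if (ch == "{") {
      j <- i + 1; states <- integer(0)
      while (chars[j] != "}") { states <- c(states, as.integer(chars[j])); j <- j + 1 }
      out <- c(out, as.integer(sum(2L^states)))
      i <- j + 1
    } else { out <- c(out, as.integer(2L^as.integer(ch))); i <- i + 1 }
  }
  out
}

# build a char_matrix from named state-string rows
cm <- function(rows, partition, outgroup, ordering = NULL) {
  cells <- do.call(rbind, lapply(rows, parse_row))
  rownames(cells) <- names(rows)
  storage.mode(cells) <- "integer"
  character_matrix(cells, partition, outgroup, ordering)
}

# random valid matrix; first taxon is the outgroup
rand_cm <- function(n_taxa, n_char, seed, p_missing = 0.1, p_poly = 0.03,
                    states = 0:1) {
  set.seed(seed)
  cells <- matrix(as.integer(2L^sample(states, n_taxa * n_char, TRUE)),
                  n_taxa, n_char)
  poly <- matrix(runif(n_taxa * n_char) < p_poly, n_taxa, n_char)
  cells[poly] <- as.integer(2L^states[1] + 2L^states[2])
  miss <- matrix(runif(n_taxa * n_char) < p_missing, n_taxa, n_char)
  cells[miss] <- NA_integer_
  rownames(cells) <- c("OUT", paste0("t", seq_len(n_taxa - 1)))
  partition <- sample(c("hard", "soft"), n_char, TRUE)
  character_matrix(cells, partition, "OUT")
}

# independent clade enumeration (ape::prop.part), non-trivial clades only
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    if (length(idx) < 2 || length(idx) >= length(labs)) return(NA_character_)
    paste(sort(labs[idx]), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

# independent parsimony length oracle via phangorn
oracle_length <- function(tree, m) {
  ss <- matrix("?", nrow(m$cells), ncol(m$cells), dimnames = dimnames(m$cells))
  for (i in seq_len(nrow(m$cells))) for (j in seq_len(ncol(m$cells))) {
    v <- m$cells[i, j]
    if (!is.na(v)) {
      bits <- which(bitwAnd(v, 2L^(0:9)) != 0L) - 1L
      ss[i, j] <- paste(bits, collapse = "")
    }
  }
  tokens <- sort(unique(as.vector(ss)))
  contrast <- matrix(0, length(tokens), 10,
                     dimnames = list(tokens, as.character(0:9)))
  for (tk in tokens) {
    if (tk == "?") contrast[tk, ] <- 1
    else contrast[tk, as.integer(strsplit(tk, "")[[1]]) + 1] <- 1
  }
  pd <- phangorn::phyDat(ss, type = "USER", contrast = contrast)
  phangorn::parsimony(tree, pd)
}

# identify which original columns survived curation by content identity
match_cols <- function(orig, cur) {
  used <- rep(FALSE, ncol(orig$cells))
  out <- integer(ncol(cur$cells))
  keep_rows <- rownames(cur$cells)
  for (j in seq_len(ncol(cur$cells))) {
    for (k in seq_len(ncol(orig$cells))) {
      if (used[k]) next
      if (identical(orig$cells[keep_rows, k], cur$cells[, j]) &&
          orig$partition[k] == cur$partition[j]) {
        out[j] <- k; used[k] <- TRUE; break
      }
    }
  }
  out
}

# identify retained original column indices after an in-order deletion
match_cols_present <- function(orig, sub) {
  kept <- integer(ncol(sub$cells))
  k <- 1
  for (j in seq_len(ncol(orig$cells))) {
    if (k > length(kept)) break
    if (identical(orig$cells[, j], sub$cells[, k]) &&
        orig$partition[j] == sub$partition[k]) {
      kept[k] <- j; k <- k + 1
    }
  }
  kept
}

# quick settings for tiny test searches
tiny_settings <- function() {
  search_settings(n_addition_replicates = 3, hold_per_replicate = 200,
                  max_trees = 200, swap = "tbr", plateau_budget = 5e4,
                  rng_seed = 1)
}
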