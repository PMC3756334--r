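#' Delete all characters of one partition
#'
#' The systematic "pseudoextinction" operator: removing the soft partition
#' simulates fossilization of every taxon at once; removing the hard
#' partition is the inverse-fossilization control.
#'
#' @param m a `char_matrix`.
#' @param which `"soft"` or `"hard"`: the partition to delete.
#' @return a `char_matrix` with the named partition removed (may have zero
#'   characters; downstream searches refuse such matrices).
#' @export
delete_partition_characters <- function(m, which = c("soft", "hard")) {
  which <- match.arg(which)
  subset_matrix(m, chars = which(m$partition != which))
}

#' Delete k characters uniformly at random
#'
#' The matched null for the node recovery test: the same number of whole
#' characters as the systematic deletion, drawn without replacement and
#' ignoring the partition. Draws that empty a partition or leave the
#' matrix uninformative are kept, not redrawn.
#'
#' @param m a `char_matrix`.
#' @param k number of characters to delete, `0 <= k < n_char`.
#' @return a `char_matrix`; deletion uses the current RNG state.
#' @export
delete_random_characters <- function(m, k) {
  nc <- ncol(m$cells)
  if (k < 0L || k >= nc)
    stop("k must satisfy 0 <= k < number of characters")
  if (k == 0L) return(m)
  drop <- sample.int(nc, k)
  subset_matrix(m, chars = setdiff(seq_len(nc), drop))
}

#' Simulate fossilization of one taxon
#'
#' Replaces every scored soft-partition cell of the named taxon with
#' MISSING; all other rows and the character set are untouched.
#'
#' @param m a `char_matrix`.
#' @param taxon taxon label.
#' @return a `char_matrix`.
#' @export
fossilize_taxon <- function(m, taxon) {
  if (!taxon %in% taxa_of(m)) stop("taxon '", taxon, "' not in matrix")
  m$cells[taxon, m$partition == "soft"] <- NA_integer_
  m
}

# number of scored soft cells a fossilization would blank
fossilizable_count <- function(m, taxon) {
  sum(!is.na(m$cells[taxon, m$partition == "soft"]))
}

#' Make one taxon randomly incomplete
#'
#' The matched null for the taxon shift test: sets `k` of the taxon's
#' currently scored cells (across both partitions) to MISSING, chosen
#' uniformly, so the row's missing-entry total matches the fossilized row
#' when `k` equals the taxon's scored soft-cell count.
#'
#' @param m a `char_matrix`.
#' @param taxon taxon label.
#' @param k number of scored cells to blank.
#' @return a `char_matrix`; deletion uses the current RNG state.
#' @export
randomize_taxon <- function(m, taxon, k) {
  if (!taxon %in% taxa_of(m)) stop("taxon '", taxon, "' not in matrix")
  scored <- which(!is.na(m$cells[taxon, ]))
  if (k > length(scored))
    stop("k exceeds the taxon's scored cell count")
  if (k == 0L) return(m)
  m$cells[taxon, scored[sample.int(length(scored), k)]] <- NA_integer_
  m
}
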