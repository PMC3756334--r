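#' Parsimony informativeness of characters
#'
#' A character is parsimony-informative when at least two states are each
#' observed unambiguously (single-state cells) in at least two taxa.
#'
#' @param m a `char_matrix`.
#' @return logical vector, one flag per character.
#' @export
is_informative <- function(m) {
  apply(m$cells, 2L, function(col) {
    col <- col[!is.na(col)]
    single <- col[vapply(col, function(v) length(state_bits(v)) == 1L, TRUE)]
    counts <- table(single)
    sum(counts >= 2L) >= 2L
  })
}

curation_report <- function(stage, removed_taxa = character(0),
                            removed_chars = integer(0), details = list()) {
  list(stage = stage, removed_taxa = removed_taxa,
       removed_chars = removed_chars, details = details)
}

#' Remove parsimony-uninformative characters
#'
#' Drops constant and autapomorphic characters; partition labels of the
#' retained characters are preserved. A matrix whose characters are all
#' uninformative is returned with zero characters and flagged for
#' exclusion in the report.
#'
#' @param m a `char_matrix`.
#' @return list with elements `matrix` and `report`.
#' @export
remove_uninformative <- function(m) {
  keep <- which(is_informative(m))
  rep <- curation_report("remove_uninformative",
                         removed_chars = setdiff(seq_len(ncol(m$cells)), keep),
                         details = list(all_uninformative = length(keep) == 0L))
  list(matrix = subset_matrix(m, chars = keep), report = rep)
}

# does row b conflict-free fit inside row a (b subsumed by a)?
row_subsumed <- function(a, b) {
  scored <- !is.na(b)
  if (any(is.na(a[scored]))) return(FALSE)       # b scores where a does not
  all(bitwAnd(a[scored], b[scored]) != 0L)
}

#' Remove taxonomic equivalents
#'
#' Within any group of taxa whose codings are identical, or where one
#' taxon's scored cells never conflict with and never exceed another's
#' (missing-data subsumption), only the first-listed taxon is retained.
#' The outgroup is never removed.
#'
#' @param m a `char_matrix`.
#' @return list with elements `matrix` and `report`.
#' @export
remove_taxonomic_equivalents <- function(m) {
  taxa <- taxa_of(m)
  drop <- logical(length(taxa))
  for (j in seq_along(taxa)) {
    if (drop[j] || taxa[j] == m$outgroup) next
    for (i in seq_along(taxa)) {
      if (i == j || drop[i]) next
      a <- m$cells[i, ]; b <- m$cells[j, ]
      if (row_subsumed(a, b)) {
        # j adds nothing beyond i; mutual subsumption (identical
        # information) keeps the first-listed
        if (!row_subsumed(b, a) || i < j || taxa[i] == m$outgroup) {
          drop[j] <- TRUE
          break
        }
      }
    }
  }
  rep <- curation_report("remove_taxonomic_equivalents",
                         removed_taxa = taxa[drop])
  list(matrix = subset_matrix(m, taxa = which(!drop)), report = rep)
}

partition_gap <- function(m) {
  abs(missing_fraction(m, "hard") - missing_fraction(m, "soft")) * 100
}

#' Balance missing data between partitions
#'
#' When the hard and soft partitions differ by 10 or more percentage
#' points of missing entries, taxa with more than 30% missing cells are
#' removed first, then characters with more than 50% missing cells,
#' iterating until the gap falls below 10 points or nothing removable
#' remains. Matrices already within 10 points are returned unchanged.
#'
#' @param m a `char_matrix`.
#' @param taxon_threshold,char_threshold removal thresholds (fractions).
#' @param gap_threshold partition gap in percentage points.
#' @param iterate single pass when `FALSE`.
#' @return list with elements `matrix` and `report`.
#' @export
balance_missing <- function(m, taxon_threshold = 0.30, char_threshold = 0.50,
                            gap_threshold = 10, iterate = TRUE) {
  removed_taxa <- character(0)
  removed_chars <- integer(0)
  gap0 <- partition_gap(m)
  repeat {
    gap <- partition_gap(m)
    if (is.nan(gap) || gap < gap_threshold) break
    taxon_miss <- rowMeans(is.na(m$cells))
    bad_taxa <- which(taxon_miss > taxon_threshold &
                        taxa_of(m) != m$outgroup)
    if (length(bad_taxa)) {
      removed_taxa <- c(removed_taxa, taxa_of(m)[bad_taxa])
      m <- subset_matrix(m, taxa = setdiff(seq_len(n_taxa(m)), bad_taxa))
      if (!iterate) break
      next
    }
    char_miss <- colMeans(is.na(m$cells))
    bad_chars <- which(char_miss > char_threshold)
    if (length(bad_chars)) {
      removed_chars <- c(removed_chars, bad_chars)
      m <- subset_matrix(m, chars = setdiff(seq_len(n_char(m)), bad_chars))
      if (!iterate) break
      next
    }
    break # nothing removable
  }
  rep <- curation_report("balance_missing",
                         removed_taxa = removed_taxa,
                         removed_chars = removed_chars,
                         details = list(gap_before = gap0,
                                        gap_after = partition_gap(m)))
  list(matrix = m, report = rep)
}

#' Inclusion thresholds for a curated matrix
#'
#' A matrix is included when it has at least `min_char` characters and
#' `min_taxa` taxa and its hard fraction `|hard| / (|hard| + |soft|)` lies
#' in `[ratio_min, ratio_max]` (boundaries inclusive).
#'
#' @param m a `char_matrix`.
#' @param min_char,min_taxa,ratio_min,ratio_max thresholds.
#' @return list with `include` (logical), `reasons` (character) and the
#'   measured quantities.
#' @export
apply_inclusion_thresholds <- function(m, min_char = 30L, min_taxa = 10L,
                                       ratio_min = 0.20, ratio_max = 0.80) {
  nc <- ncol(m$cells)
  nt <- nrow(m$cells)
  hard_ratio <- if (nc > 0) sum(m$partition == "hard") / nc else NaN
  reasons <- character(0)
  if (nc < min_char) reasons <- c(reasons, "characters")
  if (nt < min_taxa) reasons <- c(reasons, "taxa")
  if (is.nan(hard_ratio) || hard_ratio < ratio_min || hard_ratio > ratio_max)
    reasons <- c(reasons, "ratio")
  list(include = length(reasons) == 0L, reasons = reasons,
       n_char = nc, n_taxa = nt, hard_ratio = hard_ratio)
}

#' Full curation pipeline
#'
#' Applies uninformative-character removal, taxonomic-equivalent removal
#' and missing-data balancing, cycling through the three stages until a
#' fixed point is reached (a balancing removal can render further
#' characters uninformative or taxa equivalent), then evaluates the
#' inclusion thresholds. The result is idempotent and retained cell
#' values are never altered.
#'
#' Extinct taxa are not detected automatically (the compiled matrices
#' this protocol targets are neontological); taxa flagged extinct by the
#' caller are removed up front.
#'
#' @param m a `char_matrix`.
#' @param extinct taxon labels to drop before curation (never the
#'   outgroup).
#' @param ... threshold overrides passed to the stages.
#' @return list with `matrix`, `reports` (per stage pass) and `inclusion`.
#' @export
curate_matrix <- function(m, extinct = character(0), ...) {
  args <- list(...)
  reports <- list()
  if (length(extinct)) {
    extinct <- setdiff(intersect(extinct, taxa_of(m)), m$outgroup)
    m <- subset_matrix(m, taxa = setdiff(taxa_of(m), extinct))
    reports <- list(curation_report("remove_extinct", removed_taxa = extinct))
  }
  repeat {
    nt0 <- nrow(m$cells); nc0 <- ncol(m$cells)
    s1 <- remove_uninformative(m)
    s2 <- remove_taxonomic_equivalents(s1$matrix)
    s3 <- do.call(balance_missing,
                  c(list(s2$matrix),
                    args[names(args) %in% names(formals(balance_missing))]))
    reports <- c(reports, list(s1$report, s2$report, s3$report))
    m <- s3$matrix
    if (nrow(m$cells) == nt0 && ncol(m$cells) == nc0) break
    if (ncol(m$cells) == 0L || nrow(m$cells) <= 1L) break
  }
  inc <- do.call(apply_inclusion_thresholds,
                 c(list(m),
                   args[names(args) %in% names(formals(apply_inclusion_thresholds))]))
  list(matrix = m, reports = reports, inclusion = inc)
}
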