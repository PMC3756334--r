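test_that("uninformative characters are removed by definition", {
  m <- cm(c(OUT = "0000", A = "0101", B = "0110", C = "0011", D = "01?1"),
          partition = rep(c("hard", "soft"), 2), outgroup = "OUT")
  # char 1 constant, char 2 autapomorphy-free? col2 = 0,1,1,0,1 informative;
  # col3: 0,0,1,1,? informative; col4: 0,1,0,1,1 informative
  inf <- is_informative(m)
  expect_false(inf[1])
  expect_true(all(inf[2:4]))
  out <- remove_uninformative(m)
  expect_equal(ncol(out$matrix$cells), 3)
  expect_equal(out$matrix$partition, m$partition[2:4])

  # autapomorphic character removed
  m2 <- cm(c(OUT = "0", A = "1", B = "0", C = "0"),
           partition = "hard", outgroup = "OUT")
  expect_false(is_informative(m2)[1])
})

test_that("taxonomic equivalents are removed, first-listed retained", {
  m <- cm(c(OUT = "0101", A = "1100", B = "1100", C = "0011"),
          partition = rep("hard", 4), outgroup = "OUT")
  out <- remove_taxonomic_equivalents(m)
  expect_identical(out$report$removed_taxa, "B")
  expect_identical(rownames(out$matrix$cells), c("OUT", "A", "C"))

  # subsumption: B equals A with two cells missing
  m2 <- cm(c(OUT = "0101", A = "1100", B = "1?0?", C = "0011"),
           partition = rep("hard", 4), outgroup = "OUT")
  out2 <- remove_taxonomic_equivalents(m2)
  expect_identical(out2$report$removed_taxa, "B")

  # all-distinct matrix unchanged
  m3 <- cm(c(OUT = "0101", A = "1100", B = "1010", C = "0011"),
           partition = rep("hard", 4), outgroup = "OUT")
  expect_identical(remove_taxonomic_equivalents(m3)$matrix$cells, m3$cells)
})

test_that("subsumption removal matches a brute-force pairwise oracle", {
  n_removed <- 0
  for (s in 1:8) {
    m <- rand_cm(8, 10, seed = 100 + s, p_missing = 0.3)
    out <- remove_taxonomic_equivalents(m)
    # oracle: taxon j is removable if some retained i has no conflict with
    # j and scores everywhere j does
    subsumed <- function(a, b) {
      sc <- !is.na(b)
      !any(is.na(a[sc])) && all(bitwAnd(a[sc], b[sc]) != 0L)
    }
    kept <- rownames(out$matrix$cells)
    for (j in rownames(m$cells)) {
      if (j %in% kept) next
      n_removed <- n_removed + 1
      # every removed taxon must be subsumed by some kept taxon
      expect_true(any(vapply(kept, function(i)
        subsumed(m$cells[i, ], m$cells[j, ]), TRUE)),
        info = paste("seed", s, "taxon", j))
    }
    # and no kept non-outgroup taxon is strictly subsumed by another kept one
    for (j in setdiff(kept, m$outgroup)) {
      strict <- vapply(setdiff(kept, j), function(i)
        subsumed(m$cells[i, ], m$cells[j, ]) &&
          !subsumed(m$cells[j, ], m$cells[i, ]), TRUE)
      expect_false(any(strict), info = paste("seed", s, "kept", j))
    }
  }
  expect_gte(n_removed, 0)
})

test_that("missing-data balancing honours the thresholds and converges", {
  # balanced matrix untouched
  m <- rand_cm(8, 20, seed = 5, p_missing = 0.1)
  out <- balance_missing(m)
  expect_identical(out$matrix$cells, m$cells)

  # one pathological taxon drives a >10-point gap; its removal closes it
  rows <- c(OUT = "00000000", A = "01010101", B = "10101010", C = "01100110",
            D = "11001100", E = "0110?101")
  m2 <- cm(rows, partition = rep(c("hard", "soft"), each = 4), outgroup = "OUT")
  m2$cells["E", 5:8] <- NA_integer_   # soft cells of E all missing (>30% row)
  gap0 <- stemward:::partition_gap(m2)
  expect_gt(gap0, 10)
  out2 <- balance_missing(m2)
  expect_true("E" %in% out2$report$removed_taxa)
  expect_lt(out2$report$details$gap_after, 10)
})

test_that("inclusion thresholds follow the published limits", {
  mk <- function(nt, nc, nhard) {
    cells <- matrix(1L, nt, nc,
                    dimnames = list(c("OUT", paste0("t", 1:(nt - 1))), NULL))
    character_matrix(cells, rep(c("hard", "soft"), c(nhard, nc - nhard)), "OUT")
  }
  r <- apply_inclusion_thresholds(mk(15, 29, 14))
  expect_false(r$include); expect_true("characters" %in% r$reasons)
  r <- apply_inclusion_thresholds(mk(9, 40, 20))
  expect_false(r$include); expect_true("taxa" %in% r$reasons)
  # 8/40 = 0.20 exactly: boundary included
  expect_true(apply_inclusion_thresholds(mk(10, 40, 8))$include)
  # 7/40 = 0.175 < 0.20: excluded
  expect_false(apply_inclusion_thresholds(mk(10, 40, 7))$include)
  expect_true(apply_inclusion_thresholds(mk(30, 60, 30))$include)
})

test_that("flagged extinct taxa are dropped before curation", {
  m <- rand_cm(8, 20, seed = 31)
  out <- curate_matrix(m, extinct = c("t2", "t5", "OUT", "nosuch"))
  expect_false(any(c("t2", "t5") %in% rownames(out$matrix$cells)))
  expect_true("OUT" %in% rownames(out$matrix$cells))  # outgroup protected
  expect_identical(out$reports[[1]]$stage, "remove_extinct")
})

test_that("curation is idempotent and never touches retained cells", {
  for (s in 1:5) {
    m <- rand_cm(10, 25, seed = 200 + s, p_missing = 0.25)
    c1 <- curate_matrix(m)
    c2 <- curate_matrix(c1$matrix)
    expect_identical(c2$matrix$cells, c1$matrix$cells)
    expect_true(m$outgroup %in% rownames(c1$matrix$cells))
    # every retained character matches an original column bit-for-bit
    expect_true(all(match_cols(m, c1$matrix) > 0))
  }
})
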