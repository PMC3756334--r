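test_that("partition deletion removes exactly the labelled characters", {
  m <- rand_cm(8, 30, seed = 1)
  m$partition <- rep(c("hard", "soft"), c(18, 12))
  hard_only <- delete_partition_characters(m, "soft")
  expect_equal(ncol(hard_only$cells), 18)
  expect_true(all(hard_only$partition == "hard"))
  expect_identical(hard_only$cells, m$cells[, 1:18])
  # deleting the complement leaves zero characters, refused downstream
  none <- delete_partition_characters(hard_only, "hard")
  expect_equal(ncol(none$cells), 0)
  expect_error(heuristic_search(none), "characters")
})

test_that("random character deletion is uniform and seed-stable", {
  m <- rand_cm(6, 20, seed = 2)
  expect_identical(delete_random_characters(m, 0), m)
  expect_error(delete_random_characters(m, 20), "k must")

  k <- 7
  counts <- integer(20)
  n_draws <- 3000
  set.seed(99)
  for (i in seq_len(n_draws)) {
    mi <- delete_random_characters(m, k)
    kept <- match_cols_present(m, mi)
    counts[setdiff(1:20, kept)] <- counts[setdiff(1:20, kept)] + 1L
  }
  # each character deleted with frequency k/N within binomial bounds
  p <- k / 20
  bound <- 4 * sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(counts / n_draws - p) < bound))
})

test_that("fossilization blanks exactly the scored soft cells of one taxon", {
  m <- rand_cm(8, 24, seed = 3, p_missing = 0.2)
  tx <- "t3"
  scored_soft <- sum(!is.na(m$cells[tx, m$partition == "soft"]))
  mf <- fossilize_taxon(m, tx)
  expect_equal(sum(is.na(mf$cells[tx, ])) - sum(is.na(m$cells[tx, ])),
               scored_soft)
  expect_true(all(is.na(mf$cells[tx, mf$partition == "soft"])))
  # all other rows bit-identical
  others <- setdiff(rownames(m$cells), tx)
  expect_identical(mf$cells[others, ], m$cells[others, ])
  # taxon with no scored soft cells: identity
  m2 <- m; m2$cells[tx, m2$partition == "soft"] <- NA_integer_
  expect_identical(fossilize_taxon(m2, tx)$cells, m2$cells)
})

test_that("matched random degradation mirrors the fossilized row count", {
  m <- rand_cm(8, 24, seed = 4, p_missing = 0.15)
  tx <- "t5"
  k <- stemward:::fossilizable_count(m, tx)
  mf <- fossilize_taxon(m, tx)
  set.seed(10)
  mr <- randomize_taxon(m, tx, k)
  expect_equal(sum(is.na(mr$cells[tx, ])), sum(is.na(mf$cells[tx, ])))
  expect_identical(randomize_taxon(m, tx, 0L), m)
  expect_error(randomize_taxon(m, tx, 100L), "exceeds")
  set.seed(77); a <- randomize_taxon(m, tx, k)
  set.seed(77); b <- randomize_taxon(m, tx, k)
  expect_identical(a, b)
})

test_that("perturbations only blank or remove, never alter scored states", {
  m <- rand_cm(9, 30, seed = 5, p_missing = 0.2)
  set.seed(1)
  for (pert in list(fossilize_taxon(m, "t2"),
                    randomize_taxon(m, "t4", 5L))) {
    same_dim <- identical(dim(pert$cells), dim(m$cells))
    expect_true(same_dim)
    idx <- which(!is.na(pert$cells))
    expect_identical(pert$cells[idx], m$cells[idx])
  }
})
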