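test_that("tree generation is seeded, binary and outgroup-rooted", {
  sp <- synthetic_spec(n_taxa = 5, seed = 4)
  tr <- generate_tree(sp)
  expect_equal(length(tr$tip.label), 6)        # 5 ingroup + outgroup
  expect_true("OUT" %in% tr$tip.label)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  # outgroup attaches at the root
  og <- match("OUT", tr$tip.label)
  root <- length(tr$tip.label) + 1
  expect_true(any(tr$edge[, 1] == root & tr$edge[, 2] == og))
  expect_equal(ape::write.tree(generate_tree(sp)), ape::write.tree(tr))
})

test_that("evolved matrices honour their generator settings and record the truth", {
  sp <- synthetic_spec(n_taxa = 12, n_hard = 20, n_soft = 25, seed = 6)
  em <- evolve_matrix(generate_tree(sp), sp)
  m <- em$matrix
  expect_s3_class(m, "char_matrix")
  expect_equal(ncol(m$cells), 45)
  expect_equal(sum(m$partition == "hard"), 20)
  expect_equal(nrow(m$cells), 13)
  # outgroup row fully scored and all-plesiomorphic
  expect_true(all(m$cells["OUT", ] == 1L))
  expect_equal(length(em$truth$placements), 45)
  expect_gte(em$truth$n_changes, 45)
  # seeded repeat is identical
  em2 <- evolve_matrix(generate_tree(sp), sp)
  expect_identical(em2$matrix$cells, m$cells)
})

test_that("missing data stays balanced between partitions in expectation", {
  gaps <- vapply(1:10, function(s) {
    sp <- synthetic_spec(n_taxa = 15, seed = 40 + s)
    stemward:::partition_gap(evolve_matrix(generate_tree(sp), sp)$matrix)
  }, 0)
  expect_lt(mean(gaps), 10)
  expect_gte(sum(gaps < 10), 8)
})

test_that("benchmark suites are includable, seeded and span their ranges", {
  suite <- make_benchmark_suite(8, "exchangeable", n_taxa = c(10, 40),
                                n_char = 60, hard_fraction = c(0.2, 0.8),
                                seed = 77)
  expect_length(suite$matrices, 8)
  for (m in suite$matrices) {
    inc <- apply_inclusion_thresholds(m)
    expect_true(inc$include)
    expect_gte(inc$hard_ratio, 0.2)
    expect_lte(inc$hard_ratio, 0.8)
  }
  nt <- vapply(suite$matrices, function(m) nrow(m$cells), 0)
  expect_true(all(nt >= 10 & nt <= 41))
  expect_gt(max(nt) - min(nt), 3)          # sizes actually vary
  suite2 <- make_benchmark_suite(8, "exchangeable", n_taxa = c(10, 40),
                                 n_char = 60, hard_fraction = c(0.2, 0.8),
                                 seed = 77)
  expect_identical(lapply(suite2$matrices, `[[`, "cells"),
                   lapply(suite$matrices, `[[`, "cells"))
})

test_that("full crown bias makes every crown-zone change soft-owned", {
  sp <- synthetic_spec(n_taxa = 15, n_hard = 25, n_soft = 25,
                       signal_mode = "decay_biased", crown_bias = 1,
                       seed = 19)
  em <- evolve_matrix(generate_tree(sp), sp)
  zones <- vapply(em$truth$placements, `[[`, "", "zone")
  expect_true(all(em$matrix$partition[zones == "crown"] == "soft"))
  expect_gt(sum(zones == "crown"), 0)
})

test_that("label swap under exchangeability mirrors the inverse deletion", {
  m <- make_benchmark_suite(1, "exchangeable", n_taxa = 12, n_char = 40,
                            hard_fraction = 0.5, seed = 13)$matrices[[1]]
  sw <- m
  sw$partition <- ifelse(m$partition == "hard", "soft", "hard")
  expect_identical(delete_partition_characters(sw, "soft")$cells,
                   delete_partition_characters(m, "hard")$cells)
})

test_that("decay-biased suites recover fewer nodes hard-only than soft-only", {
  suite <- make_benchmark_suite(4, "decay_biased", n_taxa = c(18, 24),
                                n_char = 60, hard_fraction = c(0.4, 0.6),
                                seed = 55, homoplasy_rate = 0.2)
  res <- lapply(names(suite$matrices), function(id) {
    m <- suite$matrices[[id]]
    bench <- heuristic_search(m, desk_settings(), seed = derive_seed(1, id))
    lapply(c(foss = "fossilization", inv = "inverse_fossilization"),
           function(md) run_node_recovery(m, md, n_reps = 0,
                                          settings = desk_settings(),
                                          seed = derive_seed(2, id, md),
                                          benchmark = bench))
  })
  foss <- aggregate_node_recovery(lapply(res, `[[`, "foss"))
  inv <- aggregate_node_recovery(lapply(res, `[[`, "inv"))
  expect_lt(foss$recovery_systematic, inv$recovery_systematic)
})
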