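test_that("node recovery index follows the shared-clade definition", {
  b <- ape::read.tree(text = "(OUT,(A,(B,(C,D))));")
  expect_equal(node_recovery_index(b, b), 1)
  star <- ape::read.tree(text = "(OUT,A,B,C,D);")
  expect_equal(node_recovery_index(b, star), 0)
  expect_error(node_recovery_index(b, ape::read.tree(text = "(OUT,(A,(B,C)));")),
               "leaf sets")
  # benchmark without structure is undefined
  expect_true(is.nan(node_recovery_index(star, b)))
})

test_that("node recovery index equals the brute-force clade intersection", {
  for (s in 1:10) {
    set.seed(700 + s)
    labs <- c("OUT", paste0("t", 1:7))
    b <- ape::rtree(8, tip.label = sample(labs))
    t2 <- ape::rtree(8, tip.label = sample(labs))
    cb <- oracle_clades(b)
    expect_equal(node_recovery_index(b, t2),
                 length(intersect(cb, oracle_clades(t2))) / length(cb))
  }
})

test_that("rank-based p reproduces the published convention", {
  # 0 of 500 nulls at or below the observed value -> P = 1/501
  expect_equal(rank_p(seq(0.5, 0.9, length.out = 500), 0.1, "low"), 1 / 501)
  expect_lt(abs(rank_p(seq(0.5, 0.9, length.out = 500), 0.1, "low") - 0.002),
            5e-4)
  # 259 of 500 at or below -> P = 260/501 (about 0.52)
  null <- c(rep(0.2, 259), rep(0.9, 241))
  expect_equal(rank_p(null, 0.5, "low"), 260 / 501)
  expect_lt(abs(rank_p(null, 0.5, "low") - 0.52), 5e-3)
  # ties count toward the rank
  expect_equal(rank_p(c(0.5, 0.5, 0.7), 0.5, "low"), 3 / 4)
})

test_that("run_node_recovery wires the rank convention end to end", {
  # soft partition duplicates hard: deleting soft leaves full information,
  # so systematic recovery ties every null replicate and p is not small
  m <- rand_cm(8, 12, seed = 11, p_missing = 0)
  dup <- m
  dup$cells <- cbind(m$cells, m$cells)
  dup$partition <- rep(c("hard", "soft"), each = 12)
  dup$ordering <- rep("unordered", 24)
  r <- run_node_recovery(dup, "fossilization", n_reps = 30,
                         settings = tiny_settings(), seed = 5)
  expect_equal(r$recovery_systematic, 1)
  expect_gt(r$p_value, 0.5)
  expect_equal(r$p_value, rank_p(r$null_recovery, r$recovery_systematic, "low"))
  expect_equal(length(r$null_recovered), 30)
  expect_true(all(r$null_recovered <= r$benchmark_nodes))
})

test_that("aggregation pools raw counts, not per-matrix indices", {
  mk <- function(bench, rec, nulls) {
    structure(list(mode = "fossilization", benchmark_nodes = bench,
                   recovered_systematic = rec, recovery_systematic = rec / bench,
                   null_recovered = nulls, null_recovery = nulls / bench,
                   n_reps = length(nulls), undefined = FALSE),
              class = "node_recovery_result")
  }
  r1 <- mk(20L, 10L, c(12L, 15L, 18L))
  r2 <- mk(30L, 30L, c(20L, 25L, 30L))
  agg <- aggregate_node_recovery(list(r1, r2))
  expect_equal(agg$recovery_systematic, 40 / 50)   # not mean(0.5, 1.0)
  # i-th pooled null pairs the i-th replicates
  expect_equal(agg$null_recovery, c(32, 40, 48) / 50)
  # pooled null mean equals the benchmark-weighted mean of per-matrix nulls
  w <- c(20, 30) / 50
  expect_equal(agg$null_mean,
               mean(c(12, 15, 18) / 20) * w[1] + mean(c(20, 25, 30) / 30) * w[2])
  # single matrix: pooled equals per-matrix
  a1 <- aggregate_node_recovery(list(r1))
  expect_equal(a1$recovery_systematic, r1$recovery_systematic)
  expect_equal(a1$p_value, rank_p(r1$null_recovery, r1$recovery_systematic, "low"))
  # differing replicate counts refused
  r3 <- mk(10L, 5L, c(3L, 4L))
  expect_error(aggregate_node_recovery(list(r1, r3)), "replicate")
})
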