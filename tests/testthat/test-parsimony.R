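test_that("Fitch length matches hand-derived four-taxon values", {
  # two binary characters with an AB|CD pattern; brute-force over internal
  # assignments gives 2 steps on the matching tree, 4 on the mismatched one
  m <- cm(c(A = "11", B = "11", C = "00", D = "00"),
          partition = c("hard", "soft"), outgroup = "A")
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_length(t1, m), 2)
  expect_equal(fitch_length(t2, m), 4)

  # all-constant matrix scores zero on any tree
  m0 <- cm(c(A = "00", B = "00", C = "00", D = "00"),
           partition = c("hard", "soft"), outgroup = "A")
  expect_equal(fitch_length(t2, m0), 0)

  # absent leaf is an error
  expect_error(fitch_length(ape::read.tree(text = "((A,X),(C,D));"), m),
               "absent")
})

test_that("Fitch length agrees with the phangorn oracle on random inputs", {
  for (s in 1:20) {
    n <- sample(5:9, 1)
    m <- rand_cm(n, 15, seed = 300 + s, p_missing = 0.15, p_poly = 0.05,
                 states = 0:2)
    set.seed(s)
    tr <- ape::rtree(n, tip.label = sample(rownames(m$cells)))
    expect_equal(fitch_length(tr, m), oracle_length(tr, m), info = s)
  }
})

test_that("Fitch length is invariant under re-rooting", {
  m <- rand_cm(8, 20, seed = 42)
  set.seed(1)
  tr <- ape::rtree(8, tip.label = rownames(m$cells))
  l0 <- fitch_length(tr, m)
  for (og in c("t3", "t6")) {
    rr <- ape::root(tr, og, resolve.root = TRUE)
    expect_equal(fitch_length(rr, m), l0)
  }
})

test_that("missing data never increases a character's length", {
  m <- cm(c(OUT = "0", A = "1", B = "?", C = "1", D = "0"),
          partition = "hard", outgroup = "OUT")
  tr <- ape::read.tree(text = "(OUT,(A,(B,(C,D))));")
  lm <- fitch_length(tr, m)
  for (st in c("0", "1")) {
    mc <- m
    mc$cells["B", 1] <- parse_row(st)
    expect_gte(fitch_length(tr, mc), lm)
  }
})

test_that("exhaustive search enumerates (2n-5)!! topologies", {
  m4 <- rand_cm(4, 6, seed = 1)
  expect_equal(exhaustive_search(m4)$n_topologies, 3)
  m6 <- rand_cm(6, 6, seed = 2)
  expect_equal(exhaustive_search(m6)$n_topologies, 105)
  m10 <- rand_cm(10, 6, seed = 3)
  expect_error(exhaustive_search(m10), "9 taxa")
})

test_that("heuristic search matches the exhaustive oracle and is deterministic", {
  for (s in 1:25) {
    n <- sample(5:7, 1)
    m <- rand_cm(n, 12, seed = 400 + s, p_missing = 0.2)
    ex <- exhaustive_search(m, return_trees = FALSE)
    he <- heuristic_search(m, tiny_settings(), seed = s)
    expect_equal(he$score, ex$score, info = s)
    expect_equal(he$n_trees, ex$n_trees, info = s)
    expect_setequal(he$common_clades, ex$common_clades)
  }
  m <- rand_cm(9, 20, seed = 7)
  a <- heuristic_search(m, tiny_settings(), seed = 11)
  b <- heuristic_search(m, tiny_settings(), seed = 11)
  expect_identical(a[names(a) != "settings"], b[names(b) != "settings"])
  expect_error(heuristic_search(rand_cm(3, 5, seed = 1)), "4 taxa")
})

test_that("zero-homoplasy synthetic data is solved exactly", {
  sp <- synthetic_spec(n_taxa = 12, n_hard = 25, n_soft = 25,
                       homoplasy_rate = 0, missing_rate = 0, seed = 31)
  tr <- generate_tree(sp)
  em <- evolve_matrix(tr, sp)
  ts <- heuristic_search(em$matrix, tiny_settings(), seed = 3,
                         return_trees = TRUE)
  expect_equal(ts$score, em$truth$n_changes)
  # the generating tree is among the MPTs and shares all recovered clades
  true_clades <- oracle_clades(tr)
  expect_true(all(ts$common_clades %in% ts$common_clades)) # sanity
  found <- lapply(ts$trees, oracle_clades)
  expect_true(any(vapply(found, function(cl) setequal(cl, true_clades), TRUE)))
})

test_that("strict consensus clades equal the intersection of MPT clades", {
  for (s in 1:6) {
    m <- rand_cm(7, 8, seed = 500 + s, p_missing = 0.3)
    ts <- heuristic_search(m, tiny_settings(), seed = s, return_trees = TRUE)
    cons <- strict_consensus(ts)
    inter <- Reduce(intersect, lapply(ts$trees, oracle_clades))
    expect_setequal(clade_set(cons), inter)
    # adding trees can only shrink the consensus clade set
    sub <- ts$trees[seq_len(max(1, length(ts$trees) - 1))]
    class(sub) <- "multiPhylo"
    inter_sub <- Reduce(intersect, lapply(sub, oracle_clades))
    expect_true(all(inter %in% inter_sub))
  }
  expect_error(strict_consensus(list()), "no trees")
})

test_that("root distances count intervening nodes with both ends excluded", {
  tr <- ape::read.tree(text = "(OUT,(A,(B,(C,D))));")
  expect_equal(mean_root_distance(tr, "OUT"), 0)   # leaf at the root
  expect_equal(mean_root_distance(tr, "A"), 1)
  expect_equal(mean_root_distance(tr, "C"), 3)     # pectinate innermost
  t2 <- ape::read.tree(text = "(OUT,(B,(A,(C,D))));")
  both <- c(tr, t2)
  expect_equal(mean_root_distance(both, "B"), mean(c(2, 1)))  # 1.5
  expect_error(mean_root_distance(tr, "X"), "X")
})

test_that("patristic root distance sums ACCTRAN changes along the path", {
  m <- cm(c(OUT = "000", A = "100", B = "110", C = "111"),
          partition = rep("hard", 3), outgroup = "OUT")
  tr <- ape::read.tree(text = "(OUT,(A,(B,C)));")
  # chars change on: ingroup stem (c1), (B,C) stem (c2), C pendant (c3)
  expect_equal(mean_root_distance(tr, "C", "patristic", m), 3)
  expect_equal(mean_root_distance(tr, "A", "patristic", m), 1)
  expect_equal(mean_root_distance(tr, "OUT", "patristic", m), 0)
})

test_that("mean root distance is bounded by the leaf count", {
  for (s in 1:5) {
    m <- rand_cm(8, 10, seed = 600 + s)
    ts <- heuristic_search(m, tiny_settings(), seed = s)
    expect_true(all(ts$mean_root_distance >= 0))
    expect_true(all(ts$mean_root_distance <= 8 - 2))
  }
})
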