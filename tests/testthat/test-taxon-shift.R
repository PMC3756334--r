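test_that("shift classification follows sign and magnitude rank", {
  mk <- function(delta, p) {
    structure(list(delta = delta, p_magnitude = p),
              class = "taxon_shift_result")
  }
  expect_equal(classify_shift(mk(-0.4, 0.002)),
               list(direction = "down", significant = TRUE))
  expect_equal(classify_shift(mk(0.1, 0.40)),
               list(direction = "up", significant = FALSE))
  # zero delta is never significant regardless of p
  expect_equal(classify_shift(mk(0, 0.001)),
               list(direction = "none", significant = FALSE))
})

test_that("a taxon without scored soft cells is unperturbable", {
  m <- rand_cm(7, 16, seed = 21)
  m$cells["t2", m$partition == "soft"] <- NA_integer_
  r <- run_taxon_shift(m, "t2", n_reps = 5, settings = tiny_settings(), seed = 1)
  expect_true(r$unperturbable)
  expect_equal(r$delta, 0)
  expect_equal(r$direction, "none")
  expect_error(run_taxon_shift(m, "OUT", settings = tiny_settings()),
               "outgroup")
})

test_that("soft-only crown support produces a stemward shift", {
  # F's membership in the (E,F) cherry rests on two soft characters; its
  # deeper memberships are hard. Fossilizing F frees it to float stemward
  # within the clades its hard characters still support.
  # chars: h1 B..F, h2 C..F, h3 D..F (hard); s1, s2 E+F; s3 F only (soft)
  rows <- c(OUT = "000000", A = "000000", B = "100000", C = "110000",
            D = "111000", E = "111110", F = "111111")
  part <- c("hard", "hard", "hard", "soft", "soft", "soft")
  m <- cm(rows, part, "OUT")
  r <- run_taxon_shift(m, "F", n_reps = 10, settings = tiny_settings(), seed = 3)
  expect_lt(r$delta, 0)
  expect_equal(r$direction, "down")
  # matched null replicates blank the same number of cells
  expect_equal(r$k_deleted, 3)
})

test_that("shift summaries pool counts across taxa and datasets", {
  mk <- function(delta, p, nulls = c(0.1, -0.2)) {
    structure(list(delta = delta, p_magnitude = p, null_deltas = nulls),
              class = "taxon_shift_result")
  }
  res <- list(mk(-1, 0.01), mk(-0.5, 0.2), mk(-0.2, 0.01),
              mk(0.3, 0.01), mk(0.8, 0.6), mk(0, 0.9))
  s <- summarize_shifts(res, "fossilization")
  expect_equal(s$moved, 5)
  expect_equal(s$moved_down, 3)
  expect_equal(s$moved_up, 2)
  expect_equal(s$significant, 3)
  expect_equal(s$significant_down, 2)
  expect_equal(s$significant_up, 1)
  expect_true(s$significant <= s$moved)

  # all-zero deltas: nothing moved
  s0 <- summarize_shifts(list(mk(0, 1), mk(0, 1)), "fossilization")
  expect_equal(s0$moved, 0)

  # random condition, matched accounting: one replicate per taxon
  sr <- summarize_shifts(res, "random")
  expect_equal(sr$n, 6)
  expect_equal(sr$moved_up, 6)  # every first null delta is +0.1
  sra <- summarize_shifts(res, "random", accounting = "all_replicates")
  expect_equal(sra$n, 12)
  expect_equal(sra$moved_down, 6)
})

test_that("nodes and patristic metrics give concordant shift directions", {
  suite <- make_benchmark_suite(4, "decay_biased", n_taxa = 16, n_char = 50,
                                hard_fraction = 0.5, seed = 88,
                                homoplasy_rate = 0.5)
  agree <- 0; moved <- 0
  for (m in suite$matrices) {
    orig <- heuristic_search(m, desk_settings(), seed = 9, return_trees = TRUE)
    for (tx in setdiff(rownames(m$cells), m$outgroup)) {
      rn <- run_taxon_shift(m, tx, n_reps = 0, settings = desk_settings(),
                            seed = 9, metric = "nodes", orig = orig)
      rp <- run_taxon_shift(m, tx, n_reps = 0, settings = desk_settings(),
                            seed = 9, metric = "patristic", orig = orig)
      if (rn$direction != "none" && rp$direction != "none") {
        moved <- moved + 1
        if (rn$direction == rp$direction) agree <- agree + 1
      }
    }
  }
  expect_gt(moved, 5)
  expect_gte(agree / moved, 0.9)
})
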