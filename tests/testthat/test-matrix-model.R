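test_that("TNT fixture round-trips with its partition sidecar", {
  m <- cm(c(OUT = "0000", A = "1100", B = "1?00", C = "0011", D = "0{01}11"),
          partition = c("hard", "hard", "soft", "soft"), outgroup = "OUT")
  expect_equal(sum(m$partition == "hard"), 2)
  expect_equal(sum(m$partition == "soft"), 2)

  tmp <- tempfile(fileext = ".tnt")
  part <- tempfile(fileext = ".csv")
  write_matrix(m, tmp, "tnt", partition_path = part)
  m2 <- read_matrix(tmp, "tnt", partition = part, outgroup = "OUT")
  expect_identical(m2$cells, m$cells)
  expect_identical(m2$partition, m$partition)
  expect_identical(m2$outgroup, m$outgroup)
})

test_that("NEXUS dialect maps ?, -, and {..} correctly", {
  nex <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "  DIMENSIONS NTAX=3 NCHAR=4;",
               "  FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
               "  MATRIX",
               "    OUT 00-0",
               "    A   1?{01}1",
               "    B   0110",
               "  ;", "END;"), nex)
  m <- read_matrix(nex, "nexus", partition = rep("hard", 4), outgroup = "OUT")
  expect_true(is.na(m$cells["OUT", 3]))    # gap collapses to missing
  expect_true(is.na(m$cells["A", 2]))
  expect_equal(unname(m$cells["A", 3]), 3L)   # {01} state set
  expect_equal(unname(m$cells["B", 2]), 2L)
})

test_that("round trips are exact for both dialects on random matrices", {
  for (s in 1:6) {
    m <- rand_cm(7, 12, seed = s, p_poly = 0.1)
    for (fmt in c("nexus", "tnt")) {
      f <- tempfile(fileext = paste0(".", fmt))
      p <- tempfile(fileext = ".csv")
      write_matrix(m, f, fmt, partition_path = p)
      m2 <- read_matrix(f, fmt, partition = p, outgroup = "OUT")
      expect_identical(m2$cells, m$cells)
      expect_identical(m2$partition, m$partition)
    }
  }
})

test_that("polymorphic cells emit a braced token in NEXUS output", {
  m <- cm(c(OUT = "00", A = "{01}1", B = "11"),
          partition = c("hard", "soft"), outgroup = "OUT")
  f <- tempfile(fileext = ".nex")
  write_matrix(m, f, "nexus")
  expect_true(any(grepl("\\{01\\}", readLines(f))))
})

test_that("validation rejects bad inputs", {
  cells <- matrix(1L, 2, 4, dimnames = list(c("OUT", "A"), NULL))
  # partition length mismatch
  expect_error(character_matrix(cells, c("hard", "hard", "soft"), "OUT"),
               "partition")
  # outgroup absent
  expect_error(character_matrix(cells, rep("hard", 4), "X"), "outgroup")
  # duplicate taxon
  cells2 <- cells; rownames(cells2) <- c("A", "A")
  expect_error(character_matrix(cells2, rep("hard", 4), "A"), "duplicate")
  # empty matrix refused on write
  m <- cm(c(OUT = "01", A = "10"), c("hard", "soft"), "OUT")
  m0 <- stemward:::subset_matrix(m, chars = integer(0))
  expect_error(write_matrix(m0, tempfile(), "tnt"), "empty")
  # sidecar with too few labels
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(char_index = 1:3, label = "hard"), p, row.names = FALSE)
  f <- tempfile(fileext = ".tnt")
  write_matrix(m, f, "tnt")
  expect_error(read_matrix(f, "tnt", partition = p, outgroup = "OUT"), "2")
})

test_that("NEXUS reader agrees with ape on a polymorphism-free file", {
  m <- rand_cm(6, 10, seed = 9, p_poly = 0)
  f <- tempfile(fileext = ".nex")
  write_matrix(m, f, "nexus")
  a <- ape::read.nexus.data(f)
  expect_equal(names(a), rownames(m$cells))
  am <- do.call(rbind, lapply(a, function(x) {
    v <- suppressWarnings(as.integer(x))
    ifelse(is.na(v), NA_integer_, as.integer(2L^v))
  }))
  expect_equal(unname(am), unname(m$cells))
})
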