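test_that("PSI-BLAST ASCII PSSMs round-trip through the generator and parser", {
  ps <- make_synth_pssm(5, seed = 4)
  m <- read_pssm(ps$path)
  expect_equal(m, ps$scores, ignore_attr = TRUE)
  expect_equal(attr(m, "residues"), strsplit(ps$sequence, "")[[1]])
  # truncated row is a format error naming the line
  lines <- readLines(ps$path)
  bad <- withr::local_tempfile()
  row4 <- grep("^\\s*4\\s+[A-Z]\\s", lines)
  lines[row4] <- substr(lines[row4], 1, 60)
  writeLines(lines, bad)
  expect_error(read_pssm(bad), "malformed PSSM row")
  # sequence mismatch names the position
  wrong <- sub("^(.)(.)", "", ps$sequence)
  mism <- paste0(substr(ps$sequence, 1, 2),
                 if (substr(ps$sequence, 3, 3) == "A") "C" else "A",
                 substr(ps$sequence, 4, 5))
  expect_error(read_pssm(ps$path, expected_sequence = mism), "position 3")
})

test_that("PSSM normalisation modes behave as documented", {
  ps <- make_synth_pssm(6, seed = 2)
  m <- read_pssm(ps$path)
  expect_identical(normalize_pssm(m, "raw"), m)
  s <- normalize_pssm(m, "sigmoid")
  expect_equal(unname(s[1, 1]), unname(1 / (1 + exp(-m[1, 1]))))
  expect_true(all(s > 0 & s < 1))
  expect_equal(unname(normalize_pssm(matrix(0, 1, 20))[1, 1]), 0.5)
  expect_error(normalize_pssm(m, "weird"))
})

test_that("monogram is the PSSM row sum and is linear", {
  expect_equal(monogram(matrix(0, 1, 20)), 0)
  expect_equal(monogram(matrix(1, 1, 20)), 20)
  set.seed(5)
  m <- matrix(rnorm(7 * 20), 7, 20)
  # independent summation with a different accumulation order
  ref <- sapply(1:7, function(k) { s <- 0; for (i in 20:1) s <- s + m[k, i]; s })
  expect_equal(monogram(m), ref)
  expect_equal(monogram(3 * m), 3 * monogram(m))
})

test_that("DPC matches the brute-force triple loop and the edge-row formulas", {
  set.seed(9)
  p <- matrix(rnorm(2 * 20), 2, 20)
  d <- dpc(p)
  expect_equal(ncol(d), 400)
  expect_equal(unname(d[1, ]), as.vector(t(outer(p[1, ], p[2, ]))))
  expect_equal(unname(d[2, ]), as.vector(t(outer(p[2, ], p[1, ]))))
  for (L in c(3, 17, 50)) {
    p <- matrix(rnorm(L * 20), L, 20)
    expect_equal(unname(dpc(p)), oracle_dpc(p))
  }
  expect_equal(unname(dpc(matrix(0, 4, 20))), matrix(0, 4, 400))
  expect_error(dpc(matrix(0, 1, 20)), "at least 2")
})

test_that("physicochemical lookup returns the 7 tabled values per residue", {
  v <- physico("A")
  expect_equal(dim(v), c(1, 7))
  expect_error(physico("X"), "nonstandard")
  tab <- read_physico_table()
  expect_equal(nrow(tab), 20)
  expect_equal(unname(physico(tab$residue)), unname(as.matrix(tab[, -1])))
})

test_that("window encoding pads, maps the alphabet, and is translation-consistent", {
  s <- paste(rep("A", 40), collapse = "")
  w1 <- window_encode(s, 1)
  expect_equal(w1[1:15], rep(20L, 15))   # out-of-sequence padding
  expect_equal(window_encode(s, 20), rep(0L, 31))   # A is index 0
  seq2 <- "ACDEFGHIKLMNPQRSTVWY"
  w <- window_encode(seq2, 10)
  chars <- strsplit(seq2, "")[[1]]
  ref <- sapply(-15:15, function(o) {
    p <- 10 + o
    if (p < 1 || p > 20) 20L else match(chars[p], glycobind:::WINDOW_ALPHABET) - 1L
  })
  expect_equal(w, as.integer(ref))
  # gap characters inside the sequence map to 20
  expect_equal(window_encode("A-A", 2)[16], 20L)
  # translation consistency: prepend a gap, shift the position
  set.seed(3)
  s3 <- paste(sample(glycobind:::AA1, 50, TRUE), collapse = "")
  for (p in c(1, 7, 25, 50)) {
    expect_equal(window_encode(s3, p), window_encode(paste0("-", s3), p + 1))
  }
  expect_error(window_encode(s3, 0), "out of bounds")
  expect_error(window_encode(s3, 51), "out of bounds")
})

test_that("embedding ingestion validates shape and agrees across serialisations", {
  set.seed(8)
  m <- matrix(rnorm(10 * 1024), 10, 1024)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rds <- withr::local_tempfile(fileext = ".rds")
  write_embedding_tsv(m, tsv)
  saveRDS(m, rds)
  a <- read_embedding(tsv, expected_length = 10, expected_width = 1024)
  b <- read_embedding(rds, expected_length = 10, expected_width = 1024)
  expect_equal(a, b, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(read_embedding(tsv, expected_width = 1000), "expected 1000")
  expect_error(read_embedding(tsv, expected_length = 11), "expected 11")
})

test_that("the FNN-branch input is the 2340-wide ordered concatenation", {
  L <- 4
  p5 <- matrix(rnorm(L * 1024), L, 1024)
  st <- matrix(rnorm(L * 36), L, 36)
  es <- matrix(rnorm(L * 1280), L, 1280)
  x <- assemble_fnn_input(p5, st, es)
  expect_equal(dim(x), c(L, 2340))
  expect_equal(x[, 1025:1060], unname(st))   # ordering contract
  expect_equal(assemble_fnn_input(p5 * 0, st * 0, es * 0), matrix(0, L, 2340))
  expect_error(assemble_fnn_input(p5[1:3, ], st, es), "mismatch")
  expect_error(assemble_fnn_input(p5[, 1:100], st, es), "1024")
})
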