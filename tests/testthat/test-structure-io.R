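test_that("parsing a toy complex round-trips coordinates and separates HET groups", {
  tc <- make_toy_complex(n_residues = 12, n_binding = 3, seed = 2)
  st <- parse_structure(tc$pdb_path)
  expect_named(st$chains, "A")
  ch <- st$chains[["A"]]
  expect_equal(nrow(ch$modeled), 12)
  # PDB writes at 3 decimals: coordinates round-trip to that precision
  bb <- build_backbone(12)
  n1 <- ch$atoms[ch$atoms$elety == "N" & ch$atoms$res_index == 5, ]
  ref <- bb[bb$res_index == 5 & bb$elety == "N", ]
  expect_equal(c(n1$x, n1$y, n1$z), c(ref$x, ref$y, ref$z), tolerance = 1e-3)
  # GLC atoms live in the heteroatom set, never in modeled residues
  expect_true(all(st$het$het_code == "GLC"))
  expect_false("GLC" %in% ch$modeled$res_name3)
})

test_that("mmCIF and PDB serialisations of one fixture parse identically", {
  tc <- make_toy_complex(n_residues = 15, n_binding = 4, seed = 5)
  st_pdb <- parse_structure(tc$pdb_path)
  st_cif <- suppressWarnings(parse_structure(tc$cif_path))
  a <- st_pdb$chains[["A"]]$atoms
  b <- st_cif$chains[["A"]]$atoms
  expect_equal(a$elety, b$elety)
  expect_equal(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z), tolerance = 1e-3)
  expect_equal(st_pdb$het$het_code, st_cif$het$het_code)
})

test_that("unreadable structure files produce a parse error", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(parse_structure(bad))
  expect_error(parse_structure("no/such/file.pdb"), "not found")
})

test_that("carbohydrate atom collection honours the lexicon and heavy-atom rule", {
  tc <- make_toy_complex(n_residues = 12, n_binding = 2, seed = 3)
  st <- parse_structure(tc$pdb_path)
  # add a water and a hydrogen-bearing copy to the het table
  st$het <- dplyr::bind_rows(
    st$het,
    tibble::tibble(het_code = "HOH", elety = "O", element = "O",
                   x = 99, y = 99, z = 99, is_heavy = TRUE, chain = "A", resno = 999),
    tibble::tibble(het_code = "GLC", elety = "H1", element = "H",
                   x = 98, y = 98, z = 98, is_heavy = FALSE, chain = "A", resno = 998))
  got <- collect_carb_atoms(st, c("GLC"))
  expect_true(all(got$het_code == "GLC"))
  expect_true(all(got$is_heavy))            # hydrogen excluded
  expect_equal(nrow(collect_carb_atoms(st, "XYZ")), 0)
  expect_error(collect_carb_atoms(st, character(0)), "empty")
  # HOH can never be whitelisted
  expect_false("HOH" %in% collect_carb_atoms(st, c("GLC", "HOH"))$het_code)
})

test_that("binding annotation is inclusive at the cutoff and matches brute force", {
  res <- point_chain(matrix(c(0, 0, 0), 1))
  near <- carb_atoms_at(matrix(c(0, 0, 3.4), 1))
  far <- carb_atoms_at(matrix(c(0, 0, 3.6), 1))
  expect_equal(annotate_binding(res, near)$labels, "positive")
  expect_equal(annotate_binding(res, far)$labels, "negative")
  expect_equal(annotate_binding(res, carb_atoms_at(matrix(c(0, 0, 3.5), 1)))$labels,
               "positive")   # inclusive boundary
  # empty carbohydrate set: everything negative
  expect_equal(annotate_binding(res, near[0, ])$labels, "negative")

  # random fixture vs exhaustive all-pairs oracle
  set.seed(41)
  for (rep in 1:3) {
    n <- 20
    at <- tibble::tibble(
      res_index = rep(seq_len(n), each = 5), elety = rep(paste0("X", 1:5), n),
      element = "C", x = runif(5 * n, 0, 25), y = runif(5 * n, 0, 25),
      z = runif(5 * n, 0, 25))
    ch <- make_chain(at, rep("A", n))
    carb <- carb_atoms_at(matrix(runif(24, 0, 25), 8, 3))
    got <- which(annotate_binding(ch, carb)$labels == "positive")
    expect_equal(got, oracle_annotate(ch, carb))
  }
})

test_that("labels are invariant under atom-order permutation", {
  tc <- make_toy_complex(n_residues = 14, n_binding = 4, seed = 9)
  st <- parse_structure(tc$pdb_path)
  ch <- st$chains[["A"]]
  carb <- collect_carb_atoms(st, "GLC")
  ref <- annotate_binding(ch, carb)$labels
  set.seed(1)
  ch2 <- ch
  ch2$atoms <- ch2$atoms[sample(nrow(ch2$atoms)), ]
  expect_equal(annotate_binding(ch2, carb[sample(nrow(carb)), ])$labels, ref)
})

test_that("full-to-modeled alignment handles identity, deletions and empty chains", {
  expect_equal(align_full_to_modeled("ACDEFG", "ACDEFG"), 1:6)
  expect_equal(align_full_to_modeled("ACDEFG", "ACEFG"),
               c(1L, 2L, NA, 3L, 4L, 5L))
  expect_equal(align_full_to_modeled("ACD", ""), rep(NA_integer_, 3))
  # bijection between modeled residues and non-gap positions, random cases
  set.seed(7)
  for (rep in 1:20) {
    full <- paste(sample(glycobind:::AA1, 30, TRUE), collapse = "")
    drop <- sort(sample(30, sample(0:10, 1)))
    modeled <- paste(strsplit(full, "")[[1]][setdiff(1:30, drop)], collapse = "")
    al <- align_full_to_modeled(full, modeled)
    mapped <- al[!is.na(al)]
    expect_equal(sort(mapped), seq_len(nchar(modeled)))
    expect_equal(length(mapped), length(unique(mapped)))
  }
})

test_that("alignment score agrees with an independent global aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(13)
  sub <- matrix(-1, 20, 20, dimnames = list(glycobind:::AA1, glycobind:::AA1))
  diag(sub) <- 1
  for (rep in 1:5) {
    full <- paste(sample(glycobind:::AA1, 25, TRUE), collapse = "")
    keep <- sort(sample(25, 18))
    modeled <- paste(strsplit(full, "")[[1]][keep], collapse = "")
    al <- align_full_to_modeled(full, modeled)
    fc <- strsplit(full, "")[[1]]; mc <- strsplit(modeled, "")[[1]]
    score <- sum(ifelse(fc[!is.na(al)] == mc[al[!is.na(al)]], 1, -1)) -
      2 * sum(is.na(al))
    ref <- Biostrings::pairwiseAlignment(
      full, modeled, type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(score, as.numeric(ref))
  }
})

test_that("chain filters enforce the strict binding-count and standard-residue rules", {
  mk <- function(npos, res3 = NULL) {
    n <- 10
    ch <- point_chain(matrix(seq_len(3 * n), n, 3))
    if (!is.null(res3)) ch$modeled$res_name3[1] <- res3
    ch$labels <- c(rep("positive", npos), rep("negative", n - npos))
    ch
  }
  expect_true(chain_filters(mk(6))$keep)
  d5 <- chain_filters(mk(5))
  expect_false(d5$keep)                      # boundary: exactly 5 is dropped
  expect_match(d5$reason, "binding")
  dm <- chain_filters(mk(8, res3 = "MSE"))
  expect_false(dm$keep)
  expect_match(dm$reason, "nonstandard")
})

test_that("annotation files are an exact write/read involution", {
  ch <- point_chain(matrix(1:9, 3, 3))
  ch$labels <- c("positive", "negative", "gap")
  f <- withr::local_tempfile(fileext = ".cpb.tsv")
  write_annotation(ch, f)
  expect_equal(readLines(f)[3], "10-")
  # 50 random chains round-trip exactly
  set.seed(21)
  chains <- lapply(1:50, function(i) {
    n <- sample(5:40, 1)
    ch <- point_chain(matrix(runif(3 * n), n, 3),
                      letters = sample(glycobind:::AA1, n, TRUE))
    ch$chain_id <- paste0("ch", i)
    ch$labels <- sample(c("positive", "negative", "gap"), n, TRUE)
    ch
  })
  write_annotation(chains, f)
  back <- read_annotation(f)
  expect_equal(nrow(back), 50)
  for (i in c(1, 17, 50)) {
    expect_equal(back$chain_id[i], chains[[i]]$chain_id)
    expect_equal(back$sequence[i], chains[[i]]$full_sequence)
    expect_equal(labels_from_string(back$labels[i]), chains[[i]]$labels)
  }
  f2 <- withr::local_tempfile()
  writeLines(c(">x", "ACDE", "10-"), f2)     # short label line
  expect_error(read_annotation(f2), "x")
})
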