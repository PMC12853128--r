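test_that("ideal helix interiors are assigned the alpha-helix class", {
  ch <- helix_chain(18)
  ss <- secondary_structure(ch)
  expect_true(all(ss[5:14] == "Alpha helix"))
  expect_true(all(ss %in% SS_CLASSES))
})

test_that("short chains and one-hot encoding behave at the edges", {
  ch <- helix_chain(2)
  expect_equal(secondary_structure(ch), c("None", "None"))
  m <- assemble_structural(helix_chain(6), n_points = 120)
  expect_equal(unname(rowSums(m[, 1:9])), rep(1, 6))     # SS one-hot
  expect_equal(unname(rowSums(m[, 10:19])), rep(1, 6))   # RSA bins
})

test_that("RSA is ~1 for an isolated residue, small when buried, and clamped", {
  gly <- make_chain(tibble::tibble(res_index = 1, elety = "CA", element = "C",
                                   x = 0, y = 0, z = 0), "G")
  expect_equal(rsa(gly), 1)   # nothing occludes it; ratio > 1 clamps to 1
  # residue buried inside a dense occluding shell
  set.seed(3)
  sh <- 6 * glycobind:::sphere_points(300)
  shell <- tibble::tibble(res_index = 2, elety = paste0("S", 1:300), element = "C",
                          x = sh[, 1], y = sh[, 2], z = sh[, 3])
  core <- tibble::tibble(res_index = 1, elety = "CA", element = "C",
                         x = 0, y = 0, z = 0)
  ch <- make_chain(dplyr::bind_rows(core, shell), c("G", "G"))
  expect_lt(rsa(ch)[1], 0.1)
  expect_error(rsa_binning(1.2), "\\[0, 1\\]")
})

test_that("internal SASA tracks an independent high-resolution oracle", {
  tc <- make_toy_complex(n_residues = 15, n_binding = 0, seed = 6)
  st <- parse_structure(tc$pdb_path)
  at <- st$chains[["A"]]$atoms
  coords <- cbind(at$x, at$y, at$z)
  mine <- shrake_rupley(coords, at$element, n_points = 960)
  ref <- oracle_sasa(coords, at$element, n_points = 2000)
  max_asa <- read_max_asa()["A"]
  expect_lte(mean(abs(mine - ref) / max_asa), 0.02)
})

test_that("RSA bins have inclusive upper boundaries", {
  expect_equal(unname(which(rsa_binning(0.05)[1, ] == 1)), 1)
  expect_equal(unname(which(rsa_binning(0.1)[1, ] == 1)), 1)
  expect_equal(unname(which(rsa_binning(0.1000001)[1, ] == 1)), 2)
  expect_equal(unname(which(rsa_binning(1.0)[1, ] == 1)), 10)
  expect_equal(unname(which(rsa_binning(0)[1, ] == 1)), 1)
})

test_that("phi/psi follow the terminus convention and an independent torsion oracle", {
  ch <- helix_chain(18)
  d <- dihedrals(ch)
  expect_equal(d$phi[1], 0)
  expect_equal(d$psi[18], 0)
  # helix built from phi = -57 deg: interiors recover it
  expect_true(all(abs(d$phi[3:16] - (-57 * pi / 180)) < 0.05))
  expect_true(all(abs(d$psi[3:16] - (-47 * pi / 180)) < 0.05))
  # random quadruples vs the Gram-Schmidt oracle
  set.seed(11)
  for (rep in 1:25) {
    q <- matrix(rnorm(12), 4, 3)
    expect_equal(torsion_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                 oracle_torsion(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("neighbour counting is inclusive, symmetric, and matches brute force", {
  ch <- point_chain(rbind(c(0, 0, 0), c(13, 0, 0)))
  expect_equal(neighbor_count(ch), c(0L, 0L))
  ch3 <- point_chain(rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)))
  expect_equal(neighbor_count(ch3), c(2L, 2L, 2L))   # 12 <= 12 counts
  coil <- random_coil_chain(50, seed = 8, spread = 30)
  got <- neighbor_count(coil)
  ctr <- glycobind:::center_atoms(coil)
  brute <- sapply(1:50, function(i) {
    sum(sapply(setdiff(1:50, i), function(j) {
      sqrt(sum((ctr[i, ] - ctr[j, ])^2)) <= 12
    }))
  })
  expect_equal(got, as.integer(brute))
  # symmetry of the neighbour relation
  d <- as.matrix(dist(ctr)) <= 12
  expect_true(isSymmetric(d))
})

test_that("convex hull areas match closed forms and the facet-enumeration oracle", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(convex_hull_area(tet), sqrt(3), tolerance = 1e-9)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_area(cube), 6, tolerance = 1e-9)
  expect_equal(convex_hull_area(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))), 0)
  set.seed(5)
  for (rep in 1:10) {
    pts <- matrix(rnorm(3 * sample(5:12, 1)), ncol = 3)
    expect_equal(convex_hull_area(pts), oracle_hull_area(pts),
                 tolerance = 1e-6)
  }
})

test_that("relative positioning uses inverse index and inverse centroid distance", {
  ch <- point_chain(rbind(c(1, 0, 0), c(-1, 0, 0)))
  rp <- relative_positions(ch)
  expect_equal(rp$rel_seq_pos, c(1, 0.5))
  expect_equal(rp$rel_spa_pos, c(1, 1))   # centroid at the origin
  ch4 <- random_coil_chain(4, seed = 2)
  expect_equal(relative_positions(ch4)$rel_seq_pos, 1 / (1:4))
})

test_that("direction vectors are unit or zero with the stated conventions", {
  ch <- point_chain(rbind(c(0, 0, 0), c(2, 0, 0)))
  dv <- direction_vectors(ch)
  expect_equal(dv[2, 1:3], c(vec_prev_x = -1, vec_prev_y = 0, vec_prev_z = 0))
  expect_equal(unname(dv[1, 1:3]), c(0, 0, 0))          # no previous residue
  expect_equal(unname(dv[1, 7:9]), c(0, 0, 0))          # no CB: zero triple
  helix <- helix_chain(8)
  dvh <- direction_vectors(helix)
  norms <- sqrt(rowSums(dvh[2:7, 1:3]^2))
  expect_equal(norms, rep(1, 6), tolerance = 1e-9)
  cb_norms <- sqrt(rowSums(dvh[, 7:9]^2))                # alanine has CB
  expect_equal(cb_norms, rep(1, 8), tolerance = 1e-9)
})

test_that("backbone angles follow the parallel/antiparallel/right-angle conventions", {
  mk_co <- function(o2) {
    make_chain(tibble::tibble(
      res_index = c(1, 1, 1, 2, 2, 2),
      elety = rep(c("CA", "C", "O"), 2), element = rep(c("C", "C", "O"), 2),
      x = c(0, 1, 1, 5, 6, 6 + o2[1]), y = c(0, 0, 1, 0, 0, o2[2]),
      z = c(0, 0, 0, 0, 0, o2[3])), c("A", "A"))
  }
  expect_equal(backbone_angles(mk_co(c(0, 1, 0)))$co_angle[2], 0)       # parallel
  expect_equal(backbone_angles(mk_co(c(0, -1, 0)))$co_angle[2], pi)     # antiparallel
  ch <- point_chain(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(backbone_angles(ch)$caca_angle[2], pi / 2)
  expect_equal(backbone_angles(ch)$caca_angle[c(1, 3)], c(0, 0))        # termini
})

test_that("the descriptor is 36 wide and transforms correctly under rigid motion", {
  ch <- helix_chain(10)
  m <- assemble_structural(ch, n_points = 240)
  expect_equal(ncol(m), 36)
  # a random rotation + translation
  set.seed(17)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  shift <- c(5, -3, 2)
  ch2 <- ch
  xyz <- t(R %*% t(cbind(ch$atoms$x, ch$atoms$y, ch$atoms$z))) +
    matrix(shift, nrow(ch$atoms), 3, byrow = TRUE)
  ch2$atoms$x <- xyz[, 1]; ch2$atoms$y <- xyz[, 2]; ch2$atoms$z <- xyz[, 3]
  m2 <- assemble_structural(ch2, n_points = 240)
  scalar_cols <- setdiff(seq_len(36), 26:34)
  expect_equal(m2[, scalar_cols], m[, scalar_cols], tolerance = 1e-6)
  # the three direction vectors rotate covariantly
  for (blk in c(26, 29, 32)) {
    rotated <- t(R %*% t(m[, blk:(blk + 2)]))
    expect_equal(unname(m2[, blk:(blk + 2)]), unname(rotated), tolerance = 1e-6)
  }
  # atom-order permutation leaves the descriptor unchanged
  set.seed(4)
  ch3 <- ch
  ch3$atoms <- ch3$atoms[sample(nrow(ch3$atoms)), ]
  expect_equal(assemble_structural(ch3, n_points = 240), m, tolerance = 1e-9)
})
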