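# Synthetic fixtures: toy protein-carbohydrate complexes with planted
# binding labels, PSI-BLAST-dialect PSSM files, and class-separable
# embedding matrices.  Every generator is a pure function of its
# specification and seed.

# NeRF atom placement: position d at distance `bond` from c, angle
# `ang` (b-c-d) and dihedral `tor` (a-b-c-d).
place_atom <- function(a, b, c, bond, ang, tor) {
  bc <- unit(c - b)
  n <- unit(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

deg <- function(x) x * pi / 180

#' Build an ideal poly-alanine backbone
#'
#' Standard bond lengths/angles with the given phi/psi (omega 180); adds
#' carbonyl O and CB atoms.
#'
#' @param n Number of residues.
#' @param phi,psi Backbone dihedrals in degrees (defaults: alpha helix).
#' @return Tibble of atoms: `res_index`, `elety`, `element`, `x`, `y`, `z`.
#' @export
build_backbone <- function(n, phi = -57, psi = -47) {
  stopifnot(n >= 1)
  rows <- list()
  # seed residue
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - deg(111.2)), sin(pi - deg(111.2)), 0)
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, 1.231, deg(120.8), deg(psi) + pi)
    CB <- place_atom(N, C, CA, 1.521, deg(110.1), deg(122.6))
    rows[[i]] <- tibble(
      res_index = i,
      elety = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = c(N[1], CA[1], C[1], O[1], CB[1]),
      y = c(N[2], CA[2], C[2], O[2], CB[2]),
      z = c(N[3], CA[3], C[3], O[3], CB[3]))
    if (i < n) {
      Nn <- place_atom(N, CA, C, 1.329, deg(116.2), deg(psi))
      CAn <- place_atom(CA, C, Nn, 1.458, deg(121.7), pi)          # omega
      Cn <- place_atom(C, Nn, CAn, 1.525, deg(111.2), deg(phi))
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  bind_rows(rows)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, het = FALSE) {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, x, y, z, 1.00, 0.00, element)
}

write_toy_pdb <- function(atoms, het_atoms, path, chain = "A") {
  lines <- character(0)
  serial <- 0
  for (r in seq_len(nrow(atoms))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, atoms$elety[r], atoms$res_name3[r],
                                    chain, atoms$res_index[r],
                                    atoms$x[r], atoms$y[r], atoms$z[r],
                                    atoms$element[r]))
  }
  lines <- c(lines, "TER")
  if (!is.null(het_atoms) && nrow(het_atoms)) {
    for (r in seq_len(nrow(het_atoms))) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, het_atoms$elety[r], het_atoms$het_code[r],
                                      chain, het_atoms$resno[r],
                                      het_atoms$x[r], het_atoms$y[r], het_atoms$z[r],
                                      het_atoms$element[r], het = TRUE))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

write_toy_cif <- function(atoms, het_atoms, path, chain = "A") {
  hdr <- c("data_synthetic", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  fmt <- function(grp, id, el, name, comp, seqid, x, y, z) {
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            grp, id, el, name, comp, chain, seqid, x, y, z, seqid, comp, chain, name)
  }
  lines <- hdr
  id <- 0
  for (r in seq_len(nrow(atoms))) {
    id <- id + 1
    lines <- c(lines, fmt("ATOM", id, atoms$element[r], atoms$elety[r],
                          atoms$res_name3[r], atoms$res_index[r],
                          atoms$x[r], atoms$y[r], atoms$z[r]))
  }
  if (!is.null(het_atoms) && nrow(het_atoms)) {
    for (r in seq_len(nrow(het_atoms))) {
      id <- id + 1
      lines <- c(lines, fmt("HETATM", id, het_atoms$element[r], het_atoms$elety[r],
                            het_atoms$het_code[r], het_atoms$resno[r],
                            het_atoms$x[r], het_atoms$y[r], het_atoms$z[r]))
    }
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}

# rigid 6-carbon ring whose nearest atom sits exactly `contact` away from
# `anchor` along `dir`
carb_ring <- function(anchor, dir, contact = 3.4, radius = 0.75, resno = 900) {
  dir <- unit(dir)
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(c(dir[2] * ref[3] - dir[3] * ref[2],
              dir[3] * ref[1] - dir[1] * ref[3],
              dir[1] * ref[2] - dir[2] * ref[1]))
  center <- anchor + (contact + radius) * dir
  th <- 2 * pi * (0:5) / 6
  pts <- t(vapply(th, function(a) center - radius * cos(a) * dir + radius * sin(a) * u,
                  numeric(3)))
  tibble(het_code = "GLC", elety = paste0("C", 1:6), element = "C",
         x = pts[, 1], y = pts[, 2], z = pts[, 3], resno = resno)
}

#' Generate a toy protein-carbohydrate complex with planted labels
#'
#' An ideal poly-alanine backbone (helix or extended coil) with one rigid
#' six-atom pseudo-carbohydrate ring (HET code `GLC`) per planted binding
#' residue.  Each ring's nearest atom sits exactly 3.4 Angstrom from its
#' residue (inside the 3.5 cutoff) while staying at least 3.7 Angstrom from
#' every other residue, so the planted labels straddle the annotation
#' boundary.
#'
#' @param n_residues Chain length.
#' @param n_binding Number of planted binding residues.
#' @param geometry `"helix"` or `"coil"`.
#' @param seed Integer seed.
#' @param dir Output directory (created); default a fresh tempdir.
#' @return List: `pdb_path`, `cif_path`, `fasta_path`, `expected_labels`
#'   (over positive/negative), `binding_residues` (indices).
#' @export
make_toy_complex <- function(n_residues = 20, n_binding = 5,
                             geometry = c("helix", "coil"), seed = 1,
                             dir = tempfile("toycomplex")) {
  geometry <- match.arg(geometry)
  stopifnot(n_binding >= 0, n_binding <= n_residues)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  bb <- if (geometry == "helix") build_backbone(n_residues)
        else build_backbone(n_residues, phi = -120, psi = 120)
  bb$res_name3 <- "ALA"
  centroid <- c(mean(bb$x), mean(bb$y), mean(bb$z))

  coords <- cbind(bb$x, bb$y, bb$z)
  het <- NULL
  chosen <- integer(0)
  if (n_binding > 0) {
    candidates <- sample(n_residues)
    for (i in candidates) {
      if (length(chosen) == n_binding) break
      cb <- which(bb$res_index == i & bb$elety == "CB")
      ca <- which(bb$res_index == i & bb$elety == "CA")
      anchor <- coords[cb, ]
      side <- unit(coords[cb, ] - coords[ca, ])
      out <- unit(anchor - centroid)
      dirs <- list(side, out, unit(side + out),
                   unit(side + 0.4 * c(0, 0, 1)), unit(side - 0.4 * c(0, 0, 1)))
      for (dirv in dirs) {
        ring <- carb_ring(anchor, dirv, resno = 900 + i)
        ring_pts <- cbind(ring$x, ring$y, ring$z)
        other <- coords[bb$res_index != i, , drop = FALSE]
        dmin_other <- sqrt(min(outer(rowSums(ring_pts^2), rowSums(other^2), "+") -
                                 2 * ring_pts %*% t(other)))
        prev_ok <- is.null(het) ||
          sqrt(min(outer(rowSums(ring_pts^2), rowSums(cbind(het$x, het$y, het$z)^2), "+") -
                     2 * ring_pts %*% t(cbind(het$x, het$y, het$z)))) > 2.5
        if (dmin_other >= 3.7 && prev_ok) {
          het <- bind_rows(het, ring)
          chosen <- c(chosen, i)
          break
        }
      }
    }
    if (length(chosen) < n_binding) {
      abort(sprintf("could only place %d of %d pseudo-carbohydrates with clean margins; use a longer chain",
                    length(chosen), n_binding))
    }
  }
  chosen <- sort(chosen)
  pdb_path <- file.path(dir, "complex.pdb")
  cif_path <- file.path(dir, "complex.cif")
  fasta_path <- file.path(dir, "complex.fasta")
  write_toy_pdb(bb, het, pdb_path)
  write_toy_cif(bb, het, cif_path)
  writeLines(c(">A", paste(rep("A", n_residues), collapse = "")), fasta_path)
  labels <- rep("negative", n_residues)
  labels[chosen] <- "positive"
  list(pdb_path = pdb_path, cif_path = cif_path, fasta_path = fasta_path,
       expected_labels = labels, binding_residues = chosen)
}

#' Write a synthetic PSI-BLAST-dialect ASCII PSSM
#'
#' Valid header, then one row per residue with 20 integer log-odds in
#' `[-10, 12]`, 20 percentage columns, and the two trailing information
#' columns.  Deterministic under `seed` and parseable by [read_pssm()].
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @param path Output file (default under tempdir).
#' @param sequence Optional residue letters (defaults to a random sequence).
#' @return List with `path`, `sequence`, `scores` (the L x 20 matrix).
#' @export
make_synth_pssm <- function(length, seed = 1, path = tempfile(fileext = ".pssm"),
                            sequence = NULL) {
  set.seed(seed)
  seq_chars <- if (is.null(sequence)) sample(AA1, length, replace = TRUE)
               else strsplit(sequence, "")[[1]]
  stopifnot(length(seq_chars) == length)
  scores <- matrix(sample(-10:12, length * 20, replace = TRUE), length, 20)
  perc <- matrix(sample(0:100, length * 20, replace = TRUE), length, 20)
  aa_order <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste0("            ", paste(sprintf("%3s", c(aa_order, aa_order)), collapse = " ")))
  rows <- vapply(seq_len(length), function(k) {
    paste0(sprintf("%5d %s ", k, seq_chars[k]),
           paste(sprintf("%3d", scores[k, ]), collapse = " "), "  ",
           paste(sprintf("%3d", perc[k, ]), collapse = " "),
           sprintf("  %4.2f %8.2f", runif(1, 0, 2), runif(1, 0, 1)))
  }, character(1))
  writeLines(c(hdr, rows, "", "                      K         Lambda"), path)
  list(path = path, sequence = paste(seq_chars, collapse = ""), scores = scores)
}

#' Generate class-separable synthetic embeddings
#'
#' Two multivariate Gaussian classes in each embedding space whose means
#' differ by `d` along a random unit direction, with unit isotropic noise;
#' plus structurally valid 36-wide descriptors (proper one-hot blocks and
#' plausible ranges) and random valid window encodings.
#'
#' @param n_pos,n_neg Class sizes.
#' @param widths Embedding widths, `c(prott5, esm2)`.
#' @param d Mean separation (effect size) in each embedding space.
#' @param seed Integer seed.
#' @return List: `prott5`, `esm2`, `structural`, `windows`, `labels`.
#' @export
make_separable_embeddings <- function(n_pos, n_neg, widths = c(1024, 1280),
                                      d = 4, seed = 1) {
  stopifnot(d >= 0, n_pos >= 1, n_neg >= 1)
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(1, n_pos), rep(0, n_neg))
  gauss_block <- function(w) {
    u <- unit(rnorm(w))
    X <- matrix(rnorm(n * w), n, w)
    X + labels %o% (d * u)
  }
  prott5 <- gauss_block(widths[1])
  esm2 <- gauss_block(widths[2])
  ss <- matrix(0, n, 9); ss[cbind(1:n, sample(9, n, replace = TRUE))] <- 1
  rb <- matrix(0, n, 10); rb[cbind(1:n, sample(10, n, replace = TRUE))] <- 1
  vecs <- matrix(rnorm(n * 9), n, 9)
  for (jj in c(0, 3, 6)) {
    nr <- sqrt(rowSums(vecs[, jj + 1:3, drop = FALSE]^2))
    vecs[, jj + 1:3] <- vecs[, jj + 1:3] / nr
  }
  structural <- cbind(
    ss, rb,
    runif(n, -pi, pi), runif(n, -pi, pi),          # phi, psi
    sample(0:30, n, replace = TRUE),               # neighbour count
    runif(n, 0, 60),                               # virtual surface area
    1 / sample(1:200, n, replace = TRUE),          # rel seq pos
    runif(n, 0.02, 1),                             # rel spa pos
    vecs,
    runif(n, 0, pi), runif(n, 0, pi))              # co / caca angles
  windows <- matrix(sample(0:20, n * 31, replace = TRUE), n, 31)
  perm <- sample(n)
  list(prott5 = prott5[perm, ], esm2 = esm2[perm, ],
       structural = structural[perm, ], windows = windows[perm, ],
       labels = labels[perm])
}

#' Synthetic labeled set ready for training
#'
#' Convenience wrapper around [make_separable_embeddings()] and
#' [assemble_fnn_input()].
#'
#' @inheritParams make_separable_embeddings
#' @return A [labeled_set()].
#' @export
synth_labeled_set <- function(n_pos, n_neg, d = 4, seed = 1) {
  emb <- make_separable_embeddings(n_pos, n_neg, d = d, seed = seed)
  labeled_set(emb$windows,
              assemble_fnn_input(emb$prott5, emb$structural, emb$esm2),
              emb$labels)
}
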