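# The 36-dimensional per-residue structural descriptor:
# SS one-hot (9) + RSA bins (10) + phi + psi + neighbor count +
# virtual surface area + relative positions (2) + three direction
# vectors (9) + C=O angle + CA-CA angle.

#' The nine secondary-structure classes, in fixed encoding order
#' @export
SS_CLASSES <- c("Alpha helix", "Isolated beta-bridge", "Strand",
                "3-10 helix", "Pi helix", "Turn", "Bend", "None",
                "Irregular")

# per-residue backbone coordinate matrices (L x 3, NA where absent)
backbone_coords <- function(chain, atom_name) {
  L <- nrow(chain$modeled)
  out <- matrix(NA_real_, L, 3)
  at <- chain$atoms[chain$atoms$elety == atom_name, , drop = FALSE]
  at <- at[!duplicated(at$res_index), , drop = FALSE]
  out[at$res_index, ] <- cbind(at$x, at$y, at$z)
  out
}

# center atom = CA, falling back to the residue heavy-atom centroid
center_atoms <- function(chain) {
  ca <- backbone_coords(chain, "CA")
  miss <- which(is.na(ca[, 1]))
  for (i in miss) {
    a <- chain$atoms[chain$atoms$res_index == i & chain$atoms$is_heavy, , drop = FALSE]
    if (nrow(a)) ca[i, ] <- c(mean(a$x), mean(a$y), mean(a$z))
  }
  ca
}

# Kabsch-Sander style backbone H-bond energy matrix.
# HB[i, j] is TRUE when the N-H of residue i donates to the C=O of residue j.
hbond_matrix <- function(N, CA, C, O) {
  L <- nrow(N)
  HB <- matrix(FALSE, L, L)
  if (L < 3) return(HB)
  # amide H approximated along the previous carbonyl C->O direction
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (!anyNA(c(N[i, ], C[i - 1, ], O[i - 1, ]))) {
      H[i, ] <- N[i, ] + unit(C[i - 1, ] - O[i - 1, ])
    }
  }
  q <- 0.084 * 332
  for (i in 2:L) {
    if (anyNA(H[i, ]) || anyNA(N[i, ])) next
    for (j in seq_len(L)) {
      if (abs(i - j) < 2) next
      if (anyNA(C[j, ]) || anyNA(O[j, ])) next
      if (sum((CA[i, ] - CA[j, ])^2) > 81) next   # 9 A CA prescreen
      dON <- vnorm(O[j, ] - N[i, ]); dCH <- vnorm(C[j, ] - H[i, ])
      dOH <- vnorm(O[j, ] - H[i, ]); dCN <- vnorm(C[j, ] - N[i, ])
      if (min(dON, dCH, dOH, dCN) < 0.5) next
      E <- q * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      if (E < -0.5) HB[i, j] <- TRUE
    }
  }
  HB
}

#' Assign secondary structure from backbone geometry
#'
#' A hydrogen-bond-energy rule in the Kabsch-Sander spirit, mapped onto nine
#' classes (`r toString(SS_CLASSES)`).  `Irregular` is the catch-all for
#' assignable residues matching no pattern; residues with missing backbone
#' atoms, and all residues of chains shorter than three, are `None`.  An
#' external DSSP-style backend can be plugged in through `backend`; it must
#' return one of the same nine class names per residue.
#'
#' @param chain A [chain_record].
#' @param backend Optional function `chain -> character vector` honouring the
#'   nine-class contract; `NULL` uses the internal assignment.
#' @return Character vector (length = modeled residues) over [SS_CLASSES].
#' @export
secondary_structure <- function(chain, backend = NULL) {
  if (!is.null(backend)) {
    ss <- backend(chain)
    if (!all(ss %in% SS_CLASSES)) abort("secondary-structure backend returned classes outside the 9-class contract")
    return(ss)
  }
  L <- nrow(chain$modeled)
  N <- backbone_coords(chain, "N"); CA <- backbone_coords(chain, "CA")
  C <- backbone_coords(chain, "C"); O <- backbone_coords(chain, "O")
  missing_bb <- is.na(N[, 1]) | is.na(CA[, 1]) | is.na(C[, 1]) | is.na(O[, 1])
  if (L < 3) return(rep("None", L))
  HB <- hbond_matrix(N, CA, C, O)

  turn3 <- vapply(seq_len(L), function(i) i + 3 <= L && HB[i + 3, i], logical(1))
  turn4 <- vapply(seq_len(L), function(i) i + 4 <= L && HB[i + 4, i], logical(1))
  turn5 <- vapply(seq_len(L), function(i) i + 5 <= L && HB[i + 5, i], logical(1))

  hb <- function(i, j) i >= 1 && j >= 1 && i <= L && j <= L && HB[i, j]
  bridge <- matrix(FALSE, L, L)
  for (i in 2:(L - 1)) {
    for (j in 2:(L - 1)) {
      if (abs(i - j) <= 2) next
      par <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- rowSums(bridge) > 0
  in_ladder <- vapply(seq_len(L), function(i) {
    if (!has_bridge[i]) return(FALSE)
    js <- which(bridge[i, ])
    any(vapply(js, function(j) {
      (i > 1 && j > 1 && bridge[i - 1, j - 1]) || (i < L && j < L && bridge[i + 1, j + 1]) ||
      (i > 1 && j < L && bridge[i - 1, j + 1]) || (i < L && j > 1 && bridge[i + 1, j - 1])
    }, logical(1)))
  }, logical(1))

  helix4 <- rep(FALSE, L); helix3 <- rep(FALSE, L); helix5 <- rep(FALSE, L)
  for (i in 2:L) {
    if (turn4[i - 1] && turn4[i]) helix4[i:min(L, i + 3)] <- TRUE
    if (turn3[i - 1] && turn3[i]) helix3[i:min(L, i + 2)] <- TRUE
    if (turn5[i - 1] && turn5[i]) helix5[i:min(L, i + 4)] <- TRUE
  }
  in_turn <- rep(FALSE, L)
  for (i in seq_len(L)) {
    for (nn in 3:5) {
      if (i + nn <= L && HB[i + nn, i] && nn - 1 >= 1) {
        in_turn[(i + 1):(i + nn - 1)] <- TRUE
      }
    }
  }
  bend <- rep(FALSE, L)
  for (i in 3:(L - 2)) {
    if (anyNA(CA[c(i - 2, i, i + 2), 1])) next
    ang <- vector_angle(CA[i, ] - CA[i - 2, ], CA[i + 2, ] - CA[i, ])
    if (ang > 70 * pi / 180) bend[i] <- TRUE
  }

  ss <- rep("Irregular", L)
  ss[bend] <- "Bend"
  ss[in_turn] <- "Turn"
  ss[helix5] <- "Pi helix"
  ss[helix3] <- "3-10 helix"
  ss[in_ladder] <- "Strand"
  ss[has_bridge & !in_ladder] <- "Isolated beta-bridge"
  ss[helix4] <- "Alpha helix"
  ss[missing_bb] <- "None"
  ss
}

#' Per-residue relative solvent accessibility
#'
#' Heavy-atom Shrake-Rupley SASA summed per residue, divided by the
#' residue-type maximum from [read_max_asa()]; ratios above 1 are clamped to
#' 1.  Residues with no atoms get RSA 0.  Nonstandard residue types fall
#' back to a generic 200 A^2 maximum.
#'
#' @param chain A [chain_record].
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere test points per atom.
#' @param max_asa Named maximum-ASA vector (one-letter codes).
#' @return Numeric vector in `[0, 1]`, one value per modeled residue.
#' @export
rsa <- function(chain, probe = 1.4, n_points = 960, max_asa = read_max_asa()) {
  at <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  L <- nrow(chain$modeled)
  if (!nrow(at)) return(numeric(L))
  sasa <- shrake_rupley(cbind(at$x, at$y, at$z), at$element,
                        probe = probe, n_points = n_points)
  per_res <- vapply(seq_len(L), function(i) sum(sasa[at$res_index == i]), numeric(1))
  denom <- max_asa[chain$modeled$res_letter]
  denom[is.na(denom)] <- 200
  pmin(per_res / unname(denom), 1)
}

#' One-hot binning of an RSA value into ten bins
#'
#' Bin k covers `((k-1)/10, k/10]`, except bin 1 which covers `[0, 0.1]`.
#'
#' @param rsa_value Numeric scalar (or vector) in `[0, 1]`.
#' @return Matrix (length x 10) of 0/1 flags, each row summing to 1.
#' @export
rsa_binning <- function(rsa_value) {
  if (any(rsa_value < 0 | rsa_value > 1)) abort("RSA values must lie in [0, 1]")
  bin <- pmax(1, ceiling(rsa_value * 10 - 1e-12))
  out <- matrix(0, length(rsa_value), 10,
                dimnames = list(NULL, paste0("rsa_bin_", 1:10)))
  out[cbind(seq_along(bin), bin)] <- 1
  out
}

#' Backbone phi/psi dihedrals
#'
#' `phi(i)` from C(i-1)-N(i)-CA(i)-C(i), `psi(i)` from
#' N(i)-CA(i)-C(i)-N(i+1); radians in `(-pi, pi]`.  Angles undefined at the
#' termini or with missing atoms are reported as 0.
#'
#' @param chain A [chain_record].
#' @return Tibble with columns `phi`, `psi`.
#' @export
dihedrals <- function(chain) {
  L <- nrow(chain$modeled)
  N <- backbone_coords(chain, "N"); CA <- backbone_coords(chain, "CA")
  C <- backbone_coords(chain, "C")
  phi <- psi <- numeric(L)
  for (i in seq_len(L)) {
    if (i > 1 && !anyNA(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))) {
      phi[i] <- torsion_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < L && !anyNA(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))) {
      psi[i] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  tibble(phi = phi, psi = psi)
}

#' Count spatial neighbours within a radius
#'
#' Number of other residues whose center atom lies within `radius`
#' (inclusive) of each residue's center atom.
#'
#' @param chain A [chain_record].
#' @param radius Neighbourhood radius in Angstrom (default 12).
#' @return Integer vector of counts (self excluded).
#' @export
neighbor_count <- function(chain, radius = 12) {
  ctr <- center_atoms(chain)
  ok <- !is.na(ctr[, 1])
  L <- nrow(ctr)
  out <- integer(L)
  if (sum(ok) < 2) return(out)
  P <- ctr[ok, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(P^2), "+") - 2 * P %*% t(P)
  cnt <- rowSums(d2 <= radius^2 + 1e-9) - 1L
  out[ok] <- as.integer(cnt)
  out
}

#' Virtual surface area of each residue
#'
#' Surface area of the 3-D convex hull spanned by the residue's atoms;
#' degenerate sets (fewer than four affinely independent points) report 0.
#'
#' @param chain A [chain_record].
#' @return Numeric vector in squared Angstrom.
#' @export
virtual_surface_area <- function(chain) {
  L <- nrow(chain$modeled)
  vapply(seq_len(L), function(i) {
    a <- chain$atoms[chain$atoms$res_index == i, , drop = FALSE]
    if (!nrow(a)) return(0)
    convex_hull_area(cbind(a$x, a$y, a$z))
  }, numeric(1))
}

#' Relative sequential and spatial positioning
#'
#' `rel_seq_pos(i) = 1/i` (1-based modeled index); `rel_spa_pos(i) =
#' 1/max(d_i, eps)` where `d_i` is the distance from the residue's center
#' atom to the centroid of all center atoms and `eps = 1e-6` Angstrom.
#'
#' @param chain A [chain_record].
#' @return Tibble with columns `rel_seq_pos`, `rel_spa_pos`.
#' @export
relative_positions <- function(chain) {
  L <- nrow(chain$modeled)
  ctr <- center_atoms(chain)
  centroid <- colMeans(ctr, na.rm = TRUE)
  d <- sqrt(rowSums(sweep(ctr, 2, centroid)^2))
  d[is.na(d)] <- Inf
  tibble(rel_seq_pos = 1 / seq_len(L),
         rel_spa_pos = 1 / pmax(d, 1e-6))
}

#' Per-residue direction vectors
#'
#' Three unit vectors per residue: center(i) toward center(i-1), center(i)
#' toward center(i+1), and CA toward CB.  Undefined cases (termini; glycine
#' or missing CB) are the zero triple.
#'
#' @param chain A [chain_record].
#' @return Matrix (L x 9): prev (3), next (3), CA->CB (3).
#' @export
direction_vectors <- function(chain) {
  L <- nrow(chain$modeled)
  ctr <- center_atoms(chain)
  cb <- backbone_coords(chain, "CB")
  ca <- backbone_coords(chain, "CA")
  out <- matrix(0, L, 9, dimnames = list(NULL, c(
    paste0("vec_prev_", c("x", "y", "z")), paste0("vec_next_", c("x", "y", "z")),
    paste0("vec_cacb_", c("x", "y", "z")))))
  for (i in seq_len(L)) {
    if (i > 1 && !anyNA(ctr[c(i - 1, i), 1])) out[i, 1:3] <- unit(ctr[i - 1, ] - ctr[i, ])
    if (i < L && !anyNA(ctr[c(i, i + 1), 1])) out[i, 4:6] <- unit(ctr[i + 1, ] - ctr[i, ])
    if (!anyNA(c(ca[i, ], cb[i, ]))) out[i, 7:9] <- unit(cb[i, ] - ca[i, ])
  }
  out
}

#' Backbone carbonyl and CA-trace angles
#'
#' `co_angle(i)`: angle between the C->O bond vectors of residues i-1 and i.
#' `caca_angle(i)`: angle at CA(i) between CA(i-1)->CA(i) and
#' CA(i)->CA(i+1).  Undefined cases (termini, missing atoms) are 0.
#'
#' @param chain A [chain_record].
#' @return Tibble with columns `co_angle`, `caca_angle` (radians, `[0, pi]`).
#' @export
backbone_angles <- function(chain) {
  L <- nrow(chain$modeled)
  C <- backbone_coords(chain, "C"); O <- backbone_coords(chain, "O")
  CA <- backbone_coords(chain, "CA")
  co <- caca <- numeric(L)
  for (i in seq_len(L)) {
    if (i > 1 && !anyNA(c(C[i - 1, ], O[i - 1, ], C[i, ], O[i, ]))) {
      co[i] <- vector_angle(O[i - 1, ] - C[i - 1, ], O[i, ] - C[i, ])
    }
    if (i > 1 && i < L && !anyNA(CA[c(i - 1, i, i + 1), 1])) {
      caca[i] <- vector_angle(CA[i, ] - CA[i - 1, ], CA[i + 1, ] - CA[i, ])
    }
  }
  tibble(co_angle = co, caca_angle = caca)
}

#' Assemble the 36-dimensional structural descriptor
#'
#' Fixed concatenation order: SS one-hot (9), RSA bins (10), phi, psi,
#' neighbour count, virtual surface area, relative positions (2), three
#' direction vectors (9), C=O angle, CA-CA angle.
#'
#' @param chain A [chain_record].
#' @param ss_backend Optional secondary-structure backend
#'   (see [secondary_structure()]).
#' @param n_points Sphere points for the SASA computation.
#' @return Numeric matrix (modeled residues x 36) with named columns.
#' @export
assemble_structural <- function(chain, ss_backend = NULL, n_points = 960) {
  ss <- secondary_structure(chain, backend = ss_backend)
  ss_onehot <- matrix(0, length(ss), 9,
                      dimnames = list(NULL, paste0("ss_", 1:9)))
  ss_onehot[cbind(seq_along(ss), match(ss, SS_CLASSES))] <- 1
  rsa_v <- rsa(chain, n_points = n_points)
  parts <- list(
    ss_onehot,
    rsa_binning(rsa_v),
    as.matrix(dihedrals(chain)),
    matrix(neighbor_count(chain), ncol = 1, dimnames = list(NULL, "neighbor_count")),
    matrix(virtual_surface_area(chain), ncol = 1, dimnames = list(NULL, "virtual_surface_area")),
    as.matrix(relative_positions(chain)),
    direction_vectors(chain),
    as.matrix(backbone_angles(chain)))
  widths <- vapply(parts, ncol, integer(1))
  if (sum(widths) != 36) {
    abort(sprintf("structural descriptor assembly error: widths %s sum to %d, expected 36",
                  paste(widths, collapse = "+"), sum(widths)))
  }
  do.call(cbind, parts)
}

#' Structural features as a tibble
#'
#' @param chain A [chain_record].
#' @inheritParams assemble_structural
#' @return Tibble: `res_index`, `res_letter`, then the 36 descriptor columns.
#' @export
featurize_structure <- function(chain, ss_backend = NULL, n_points = 960) {
  m <- assemble_structural(chain, ss_backend = ss_backend, n_points = n_points)
  bind_cols(chain$modeled[, c("res_index", "res_letter")], as_tibble(m))
}
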