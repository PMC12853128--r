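# In-code fixture builders shared across test files.

# a chain_record built directly from an atom table (res_index, elety,
# element, x, y, z) and one-letter residue codes
make_chain <- function(atoms, letters, res_name3 = NULL) {
  L <- length(letters)
  res_name3 <- res_name3 %||% glycobind:::AA3[match(letters, glycobind:::AA1)]
  modeled <- tibble::tibble(res_index = seq_len(L), resno = seq_len(L),
                            res_name3 = res_name3, res_letter = letters)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  glycobind:::new_chain_record(
    chain_id = "A", full_sequence = paste(letters, collapse = ""),
    modeled = modeled, atoms = tibble::as_tibble(atoms),
    alignment = seq_len(L))
}

# chain with one atom ("CA") per residue at the given coordinate rows
point_chain <- function(coords, letters = rep("A", nrow(coords))) {
  n <- nrow(coords)
  make_chain(tibble::tibble(res_index = seq_len(n), elety = "CA", element = "C",
                            x = coords[, 1], y = coords[, 2], z = coords[, 3]),
             letters)
}

carb_atoms_at <- function(coords, element = "C") {
  tibble::tibble(het_code = "GLC", elety = paste0("C", seq_len(nrow(coords))),
                 element = element, x = coords[, 1], y = coords[, 2],
                 z = coords[, 3], is_heavy = element != "H",
                 chain = "A", resno = 900)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an ideal-helix chain_record straight from the backbone builder
helix_chain <- function(n = 18) {
  bb <- glycobind::build_backbone(n)
  make_chain(bb[, c("res_index", "elety", "element", "x", "y", "z")],
             rep("A", n))
}

random_coil_chain <- function(n, seed = 1, spread = 12) {
  set.seed(seed)
  point_chain(matrix(runif(n * 3, 0, spread), n, 3))
}
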