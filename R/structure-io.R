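# Structure parsing, carbohydrate lookup, binding annotation, and the
# FASTA <-> modeled-residue alignment.

#' Read a carbohydrate HET-code lexicon
#'
#' One three-letter chemical component code per line; `#` comments allowed.
#' Codes are upper-cased and de-duplicated.  Water (`HOH`) is never accepted
#' as a carbohydrate and is silently dropped with a warning if present.
#'
#' @param path Path to a lexicon file; defaults to the editable list shipped
#'   with the package.
#' @return Character vector of unique upper-case HET codes.
#' @export
read_carb_lexicon <- function(path = NULL) {
  path <- path %||% gb_extdata("carb_lexicon.txt")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  codes <- toupper(trimws(lines))
  codes <- unique(codes[nzchar(codes)])
  if ("HOH" %in% codes) {
    warn("'HOH' found in carbohydrate lexicon; water is never a carbohydrate and was removed")
    codes <- setdiff(codes, "HOH")
  }
  codes
}

element_from_atom <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    # fall back to the leading letters of the atom name
    guess <- gsub("[^A-Za-z].*$", "", trimws(elety[miss]))
    guess <- toupper(substr(guess, 1, 1))
    el[miss] <- guess
  }
  el
}

# Keep only the highest-occupancy alternate conformer per (residue, atom name).
resolve_altloc <- function(atoms) {
  if (!nrow(atoms)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  o <- atoms$o
  o[is.na(o)] <- 1
  ord <- order(key, -o)
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]   # restore author (file) order
}

new_chain_record <- function(chain_id, full_sequence, modeled, atoms,
                             alignment = NULL, labels = NULL) {
  structure(
    list(chain_id = chain_id, full_sequence = full_sequence,
         modeled = modeled, atoms = atoms,
         alignment = alignment, labels = labels),
    class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain_record %s> %d modeled residues, full sequence length %d\n",
              x$chain_id, nrow(x$modeled), nchar(x$full_sequence)))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive / %d negative / %d gap\n",
                sum(x$labels == "positive"), sum(x$labels == "negative"),
                sum(x$labels == "gap")))
  }
  invisible(x)
}

#' Parse a protein structure file into per-chain records
#'
#' Reads PDB or mmCIF (via bio3d), splits polymer chains from heteroatoms,
#' resolves alternate conformers to the highest-occupancy copy, and flags
#' hydrogens.  The returned object holds one [chain_record] per polymer chain
#' (residues in author order) plus a separate heteroatom table for ligand
#' lookup.  Until a FASTA is attached with [attach_full_sequence()], each
#' chain's `full_sequence` is its modeled sequence with an identity alignment.
#'
#' @param path Structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `structure_set`: list with elements `chains` (named list of
#'   `chain_record`) and `het` (tibble of heteroatoms).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("could not parse ", format, " file '",
                                     path, "': ", conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (!nrow(at)) {
    abort(sprintf("could not parse %s file '%s': no ATOM/HETATM records found",
                  format, path))
  }
  if (!"insert" %in% names(at)) at$insert <- NA_character_
  if (!"o" %in% names(at)) at$o <- 1
  at$element <- element_from_atom(at$elesy, at$elety)
  at$is_heavy <- !(at$element %in% c("H", "D"))
  at <- resolve_altloc(at)

  poly <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type != "ATOM", , drop = FALSE]
  het_tbl <- tibble(
    het_code = toupper(het$resid), elety = het$elety, element = het$element,
    x = het$x, y = het$y, z = het$z, is_heavy = het$is_heavy,
    chain = het$chain, resno = het$resno)

  chains <- list()
  for (ch in unique(poly$chain)) {
    pc <- poly[poly$chain == ch, , drop = FALSE]
    rid <- paste(pc$resno, ifelse(is.na(pc$insert), "", pc$insert))
    ures <- unique(rid)
    if (!length(ures)) {
      warn(sprintf("chain %s has zero residues; skipped", ch))
      next
    }
    res_index <- match(rid, ures)
    modeled <- tibble(
      res_index = seq_along(ures),
      resno = pc$resno[match(ures, rid)],
      res_name3 = toupper(pc$resid[match(ures, rid)]),
      res_letter = aa3_to_1(pc$resid[match(ures, rid)]))
    atoms <- tibble(
      res_index = res_index, elety = pc$elety, element = pc$element,
      x = pc$x, y = pc$y, z = pc$z, is_heavy = pc$is_heavy)
    seq_mod <- paste(modeled$res_letter, collapse = "")
    chains[[ch]] <- new_chain_record(
      chain_id = ch, full_sequence = seq_mod, modeled = modeled, atoms = atoms,
      alignment = seq_len(nrow(modeled)))
  }
  structure(list(chains = chains, het = het_tbl), class = "structure_set")
}

#' Collect carbohydrate heavy atoms from a parsed structure
#'
#' @param structure A `structure_set` from [parse_structure()].
#' @param lexicon Character vector of carbohydrate HET codes
#'   (see [read_carb_lexicon()]).
#' @return Tibble of heavy atoms belonging to HET groups in the lexicon.
#' @export
collect_carb_atoms <- function(structure, lexicon) {
  if (length(lexicon) == 0) {
    abort("empty carbohydrate lexicon: refusing to annotate with no carbohydrate codes (configuration mistake)")
  }
  lexicon <- setdiff(toupper(lexicon), "HOH")
  het <- structure$het
  het[het$het_code %in% lexicon & het$is_heavy, , drop = FALSE]
}

#' Global alignment of a full (FASTA) sequence onto the modeled sequence
#'
#' Needleman-Wunsch with match +1, mismatch -1, gap -2 (linear).  The
#' traceback is deterministic with preference diagonal > up > left, which
#' places unavoidable gaps later in the full sequence.  Every modeled residue
#' must be consumed; full-sequence positions left unmatched map to `NA`
#' (gap).
#'
#' @param full_sequence,modeled_sequence Upper-case amino-acid strings.
#' @return Integer vector of length `nchar(full_sequence)`: the modeled
#'   residue index matched to each full-sequence position, or `NA` for gap.
#' @export
align_full_to_modeled <- function(full_sequence, modeled_sequence) {
  a <- strsplit(full_sequence, "")[[1]]
  b <- strsplit(modeled_sequence, "")[[1]]
  n <- length(a); m <- length(b)
  if (m == 0) return(rep(NA_integer_, n))
  gap <- -2
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, 1, -1)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  align <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    s <- S[i + 1, j + 1]
    if (s == S[i, j] + (if (a[i] == b[j]) 1 else -1)) {
      align[i] <- j; i <- i - 1; j <- j - 1
    } else if (s == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  if (j > 0 || anyDuplicated(stats::na.omit(align))) {
    abort("alignment failed to consume every modeled residue exactly once; modeled sequence is not embeddable in the full sequence under NW(+1/-1/-2)")
  }
  align
}

#' Attach the full (FASTA) sequence to a chain and align it
#'
#' @param chain A [chain_record].
#' @param full_sequence The chain's full sequence, e.g. from the FASTA
#'   deposited alongside the structure.
#' @return The chain with `full_sequence` and `alignment` set (labels, if
#'   present, are invalidated).
#' @export
attach_full_sequence <- function(chain, full_sequence) {
  full_sequence <- toupper(gsub("\\s", "", full_sequence))
  modeled_seq <- paste(chain$modeled$res_letter, collapse = "")
  chain$full_sequence <- full_sequence
  chain$alignment <- align_full_to_modeled(full_sequence, modeled_seq)
  chain$labels <- NULL
  chain
}

#' Annotate carbohydrate-binding residues by heavy-atom distance
#'
#' A modeled residue is labeled `positive` when any of its heavy atoms lies
#' within `cutoff` (inclusive) of any carbohydrate heavy atom; other modeled
#' residues are `negative`; unmodeled full-sequence positions are `gap`.
#'
#' @param chain A [chain_record] with alignment set.
#' @param carb_atoms Tibble from [collect_carb_atoms()]; may have zero rows,
#'   in which case every modeled residue is negative.
#' @param cutoff Distance threshold in Angstrom (default 3.5, inclusive).
#' @return The chain with `labels` filled in.
#' @export
annotate_binding <- function(chain, carb_atoms, cutoff = 3.5) {
  at <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  pos_idx <- integer(0)
  if (nrow(carb_atoms) > 0 && nrow(at) > 0) {
    carb <- carb_atoms[carb_atoms$is_heavy, , drop = FALSE]
    if (nrow(carb) > 0) {
      A <- cbind(at$x, at$y, at$z)
      C <- cbind(carb$x, carb$y, carb$z)
      # squared distances, atoms x carb
      d2 <- outer(rowSums(A^2), rowSums(C^2), "+") - 2 * A %*% t(C)
      near <- rowSums(d2 <= cutoff^2 + 1e-12) > 0
      pos_idx <- unique(at$res_index[near])
    }
  }
  L <- nchar(chain$full_sequence)
  labels <- rep("gap", L)
  mapped <- !is.na(chain$alignment)
  labels[mapped] <- ifelse(chain$alignment[mapped] %in% pos_idx,
                           "positive", "negative")
  chain$labels <- labels
  chain
}

#' Decide whether an annotated chain enters the dataset
#'
#' A chain is kept only if it has strictly more than `min_binding` positive
#' residues and every modeled residue is one of the 20 standard amino acids.
#'
#' @param chain Annotated [chain_record].
#' @param min_binding Positive-count threshold (strict; default 5).
#' @return A list with `keep` (logical) and `reason` (string).
#' @export
chain_filters <- function(chain, min_binding = 5) {
  if (is.null(chain$labels)) abort("chain has no labels; run annotate_binding() first")
  nonstd <- !(chain$modeled$res_name3 %in% AA3)
  if (any(nonstd)) {
    return(list(keep = FALSE,
                reason = sprintf("nonstandard residue type(s): %s",
                                 paste(unique(chain$modeled$res_name3[nonstd]),
                                       collapse = ","))))
  }
  npos <- sum(chain$labels == "positive")
  if (npos <= min_binding) {
    return(list(keep = FALSE,
                reason = sprintf("only %d binding residues (need > %d)",
                                 npos, min_binding)))
  }
  list(keep = TRUE, reason = sprintf("%d binding residues, all-standard chain", npos))
}

label_to_char <- c(positive = "1", negative = "0", gap = "-")

#' Write / read per-chain binding annotations
#'
#' Plain-text records of three lines per chain: a FASTA-style header, the
#' full sequence, and an equal-length label string over `{1, 0, -}`
#' (binding / non-binding / unmodeled).  `read_annotation` inverts
#' `write_annotation` exactly.
#'
#' @param chains A list of annotated [chain_record]s.
#' @param path Output file (conventionally `*.cpb.tsv`).
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a tibble with columns `chain_id`, `sequence`, `labels`.
#' @export
write_annotation <- function(chains, path) {
  if (inherits(chains, "chain_record")) chains <- list(chains)
  lines <- unlist(lapply(chains, function(ch) {
    if (is.null(ch$labels)) abort(paste0("chain ", ch$chain_id, " has no labels"))
    c(paste0(">", ch$chain_id),
      ch$full_sequence,
      paste(label_to_char[ch$labels], collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) abort("malformed annotation file: records are not triplets of header/sequence/labels")
  idx <- seq(1, length(lines), by = 3)
  recs <- lapply(idx, function(i) {
    id <- sub("^>", "", lines[i])
    seqs <- lines[i + 1]
    labs <- lines[i + 2]
    if (nchar(labs) != nchar(seqs)) {
      abort(sprintf("annotation record '%s': label line length %d != sequence length %d",
                    id, nchar(labs), nchar(seqs)))
    }
    if (grepl("[^10-]", labs)) abort(sprintf("annotation record '%s': labels must be over {1,0,-}", id))
    tibble(chain_id = id, sequence = seqs, labels = labs)
  })
  bind_rows(recs)
}

#' Convert a label string back to the long form
#' @param labels String over `{1,0,-}`.
#' @return Character vector over `positive`/`negative`/`gap`.
#' @export
labels_from_string <- function(labels) {
  ch <- strsplit(labels, "")[[1]]
  unname(c(`1` = "positive", `0` = "negative", `-` = "gap")[ch])
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(toupper(seqs), rownames(fa$ali))
}
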