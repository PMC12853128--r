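# PSSM ingestion and derived evolutionary features, physicochemical lookup,
# residue-window index encoding, embedding-matrix ingestion, and assembly of
# the 2340-wide FNN-branch input.

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue whose first 20 numeric columns are the log-odds scores (the
#' following 20 percentage columns are checked for presence and discarded).
#'
#' @param path PSSM file.
#' @param expected_sequence Optional sequence; the per-row residue letters
#'   are checked against it.
#' @return Numeric matrix (L x 20), columns named in PSI-BLAST amino-acid
#'   order, with the residue letters as a `residues` attribute.
#' @export
read_pssm <- function(path, expected_sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!length(rows)) abort(paste0("no PSSM rows found in '", path, "'"))
  letters_col <- character(0)
  scores <- list()
  for (li in rows) {
    fields <- strsplit(trimws(lines[li]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (length(nums) < 40 || anyNA(nums[1:40])) {
      abort(sprintf("malformed PSSM row at line %d: expected 40 numeric fields (20 log-odds + 20 percentages), found %d",
                    li, sum(!is.na(nums))))
    }
    letters_col <- c(letters_col, fields[2])
    scores[[length(scores) + 1]] <- nums[1:20]
  }
  mat <- do.call(rbind, scores)
  colnames(mat) <- c("A","R","N","D","C","Q","E","G","H","I",
                     "L","K","M","F","P","S","T","W","Y","V")
  attr(mat, "residues") <- letters_col
  if (!is.null(expected_sequence)) {
    exp <- strsplit(toupper(expected_sequence), "")[[1]]
    if (length(exp) != length(letters_col)) {
      abort(sprintf("PSSM has %d rows but expected sequence has %d residues",
                    length(letters_col), length(exp)))
    }
    bad <- which(exp != letters_col)
    if (length(bad)) {
      abort(sprintf("PSSM residue mismatch at position %d: file '%s' vs expected '%s'",
                    bad[1], letters_col[bad[1]], exp[bad[1]]))
    }
  }
  mat
}

#' Normalise a PSSM
#'
#' `raw` returns the log-odds unchanged; `sigmoid` maps them elementwise
#' through `1/(1+exp(-x))` (the default scaling used ahead of the derived
#' features).
#'
#' @param pssm L x 20 matrix.
#' @param mode `"sigmoid"` or `"raw"`.
#' @return Matrix of the same shape.
#' @export
normalize_pssm <- function(pssm, mode = c("sigmoid", "raw")) {
  mode <- match.arg(mode)
  if (mode == "raw") return(pssm)
  out <- 1 / (1 + exp(-pssm))
  attributes(out) <- attributes(pssm)
  out
}

#' Monogram feature: per-residue PSSM row sum
#'
#' @param pssm L x 20 matrix.
#' @return Numeric vector of length L.
#' @export
monogram <- function(pssm) {
  if (ncol(pssm) != 20) abort("PSSM must have exactly 20 columns")
  unname(rowSums(pssm))
}

#' Dipeptide-composition feature from a PSSM
#'
#' For each residue k a 20 x 20 block of products with the neighbouring
#' rows: the first row uses the next row only, the last row the previous
#' row only, and interior rows the sum of both:
#' `DPC(k,i,j) = P[k,i]*P[k-1,j] + P[k,i]*P[k+1,j]`.
#' Each block is flattened row-major (i outer, j inner) to width 400.
#'
#' @param pssm L x 20 matrix with L >= 2.
#' @return Numeric matrix (L x 400).
#' @export
dpc <- function(pssm) {
  if (ncol(pssm) != 20) abort("PSSM must have exactly 20 columns")
  L <- nrow(pssm)
  if (L < 2) abort("DPC needs at least 2 residues (both neighbours undefined for L < 2)")
  out <- matrix(0, L, 400)
  for (k in seq_len(L)) {
    block <- matrix(0, 20, 20)
    if (k > 1) block <- block + outer(pssm[k, ], pssm[k - 1, ])
    if (k < L) block <- block + outer(pssm[k, ], pssm[k + 1, ])
    out[k, ] <- as.vector(t(block))   # row-major: i outer, j inner
  }
  colnames(out) <- paste0("dpc_", rep(1:20, each = 20), "_", rep(1:20, 20))
  out
}

#' Physicochemical property vector for a residue
#'
#' @param residue_letter One-letter code(s) among the 20 standard residues.
#' @param table Property table from [read_physico_table()].
#' @return Numeric matrix (length x 7).
#' @export
physico <- function(residue_letter, table = read_physico_table()) {
  i <- match(toupper(residue_letter), table$residue)
  if (anyNA(i)) {
    abort(sprintf("no physicochemical values for nonstandard residue '%s'",
                  residue_letter[which(is.na(i))[1]]))
  }
  m <- as.matrix(table[i, -1, drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Encode a 31-residue window as alphabet indices
#'
#' The 20 residues and the gap, `"ARNDCQEGHILKMFPSTWYV-"`, are numbered 0
#' to 20.  For a target position the window spans 15 positions upstream and
#' 15 downstream; positions outside the sequence, gap characters, and any
#' non-standard letter map to index 20.
#'
#' @param sequence Sequence string (may contain `-` for unmodeled positions).
#' @param position 1-based target position.
#' @return Integer vector of 31 indices in `[0, 20]`.
#' @export
window_encode <- function(sequence, position) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (position < 1 || position > L) {
    abort(sprintf("position %d out of bounds for sequence of length %d", position, L))
  }
  idx <- (position - 15):(position + 15)
  out <- rep(20L, 31)
  inside <- idx >= 1 & idx <= L
  m <- match(chars[idx[inside]], WINDOW_ALPHABET) - 1L
  m[is.na(m)] <- 20L
  out[inside] <- m
  out
}

#' Window-encode every position of a sequence
#' @inheritParams window_encode
#' @return Integer matrix (nchar(sequence) x 31).
#' @export
window_encode_all <- function(sequence) {
  L <- nchar(sequence)
  t(vapply(seq_len(L), function(p) window_encode(sequence, p), integer(31)))
}

#' Read a pre-computed per-residue embedding matrix
#'
#' Embeddings (e.g. from protein language models) are computed outside this
#' package and ingested as numeric matrices, rows = residues.  Supported
#' serialisations: headerless TSV (`.tsv`/`.txt`) and RDS (`.rds`).
#'
#' @param path Matrix file.
#' @param expected_length Required row count (residues); `NULL` skips the check.
#' @param expected_width Required column count (e.g. 1024 or 1280); `NULL`
#'   skips the check.
#' @param source_tag Free-text provenance tag stored on the result.
#' @return Numeric matrix with a `source_tag` attribute.
#' @export
read_embedding <- function(path, expected_length = NULL, expected_width = NULL,
                           source_tag = basename(path)) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    m <- readRDS(path)
    if (!is.matrix(m)) m <- as.matrix(m)
  } else {
    m <- as.matrix(read.delim(path, header = FALSE))
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (!is.null(expected_length) && nrow(m) != expected_length) {
    abort(sprintf("embedding row mismatch: expected %d residues, found %d",
                  expected_length, nrow(m)))
  }
  if (!is.null(expected_width) && ncol(m) != expected_width) {
    abort(sprintf("embedding width mismatch: expected %d, found %d",
                  expected_width, ncol(m)))
  }
  if (!all(is.finite(m))) abort("embedding contains non-finite entries")
  attr(m, "source_tag") <- source_tag
  m
}

#' Write an embedding matrix as headerless TSV
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_embedding_tsv <- function(m, path) {
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the FNN-branch input
#'
#' Per-residue concatenation `prott5 (1024) || structural (36) || esm2
#' (1280)`, total width 2340.  All three sources must agree on the residue
#' count.
#'
#' @param prott5 L x 1024 embedding matrix.
#' @param structural L x 36 structural descriptor matrix.
#' @param esm2 L x 1280 embedding matrix.
#' @return Numeric matrix (L x 2340).
#' @export
assemble_fnn_input <- function(prott5, structural, esm2) {
  if (ncol(prott5) != 1024) abort(sprintf("first block must be 1024 wide, got %d", ncol(prott5)))
  if (ncol(structural) != 36) abort(sprintf("structural block must be 36 wide, got %d", ncol(structural)))
  if (ncol(esm2) != 1280) abort(sprintf("last block must be 1280 wide, got %d", ncol(esm2)))
  ns <- c(nrow(prott5), nrow(structural), nrow(esm2))
  if (length(unique(ns)) != 1) {
    abort(sprintf("row-count mismatch across feature sources: %s", paste(ns, collapse = "/")))
  }
  out <- cbind(prott5, as.matrix(structural), esm2)
  dimnames(out) <- NULL
  out
}
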