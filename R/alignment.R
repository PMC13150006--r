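#' Construct an amino-acid alignment
#'
#' An alignment is stored as a character matrix (one row per sequence, one
#' column per alignment position) of upper-case one-letter residue codes with
#' \code{"-"} for gaps. Columns are indexed 1-based throughout the package.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @param ids sequence identifiers (defaults to names of \code{seqs}).
#' @param ambiguous_to_gap map the ambiguity/non-standard codes
#'   B, Z, X, U, O, J to gap instead of rejecting them. The default is to
#'   reject: subfamily sequence sets from curated databases are expected to be
#'   clean.
#' @return An object of class \code{"aa_alignment"}: the character matrix with
#'   sequence identifiers as row names.
#' @export
alignment <- function(seqs, ids = names(seqs), ambiguous_to_gap = FALSE) {
  if (length(seqs) < 1L) sx_error("selexp_empty_alignment", "alignment needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    sx_error("selexp_alignment_shape",
             sprintf("ragged alignment: record '%s' has length %d, expected %d",
                     bad, lens[ids == bad][1L], lens[1L]))
  }
  if (lens[1L] < 1L) sx_error("selexp_alignment_shape", "zero-length sequences")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  if (ambiguous_to_gap) m[m %in% AMBIGUOUS] <- GAP
  allowed <- c(AA20, GAP)
  bad <- which(!(m %in% allowed))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    sx_error("selexp_parse",
             sprintf("illegal character '%s' in record '%s' at column %d",
                     m[bad[1L]], rownames(m)[i[1L]], i[2L]))
  }
  structure(m, class = "aa_alignment")
}

#' Read an aligned FASTA file
#'
#' Sequences are upper-cased and \code{"."} is treated as a gap synonym. All
#' records must have identical length.
#'
#' @param path FASTA file of aligned sequences.
#' @param format only \code{"fasta"} is supported.
#' @inheritParams alignment
#' @return An \code{"aa_alignment"} (see [alignment()]).
#' @export
read_alignment <- function(path, format = "fasta", ambiguous_to_gap = FALSE) {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) sx_error("selexp_parse", sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  alignment(as.character(set), ids = ids, ambiguous_to_gap = ambiguous_to_gap)
}

#' Write an alignment to FASTA
#'
#' @param aln an \code{"aa_alignment"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  set <- Biostrings::BStringSet(apply(unclass(aln), 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 5L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Read a generic-number annotation table
#'
#' Two tab-separated columns: reference residue position (1-based, counting
#' non-gap characters of the reference row) and generic number (e.g.
#' \code{3x36}). Lines starting with \code{#} are comments.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{position} (integer) and
#'   \code{generic_number} (character).
#' @export
read_numbering <- function(path) {
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("position", "generic_number"),
                          colClasses = c("integer", "character"))
  df
}

#' Attach generic residue numbering to alignment columns
#'
#' Maps annotated residue positions of a reference sequence (1-based, counting
#' its non-gap characters) to alignment columns, yielding a column-to-generic-
#' number map. Unannotated columns are absent from the map. The mapping is
#' unaffected by all-gap columns inserted into the alignment because positions
#' are expressed in reference-residue coordinates.
#'
#' @param aln an \code{"aa_alignment"}.
#' @param annotation data.frame with columns \code{position},
#'   \code{generic_number} (see [read_numbering()]), or a path to such a TSV.
#' @param reference_id identifier of the reference row in \code{aln}.
#' @return An object of class \code{"generic_number_map"}: data.frame with
#'   columns \code{column} (1-based alignment column) and
#'   \code{generic_number}, with attribute \code{reference_id}.
#' @export
attach_numbering <- function(aln, annotation, reference_id) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_numbering(annotation)
  }
  if (!reference_id %in% rownames(aln)) {
    sx_error("selexp_unknown_reference",
             sprintf("reference id '%s' not found in alignment", reference_id))
  }
  if (nrow(annotation) == 0L) {
    return(structure(data.frame(column = integer(), generic_number = character()),
                     class = c("generic_number_map", "data.frame"),
                     reference_id = reference_id, alignment_length = ncol(aln)))
  }
  parse_generic_number(annotation$generic_number)  # validates label syntax
  if (anyDuplicated(annotation$generic_number)) {
    sx_error("selexp_duplicate_generic_number",
             sprintf("duplicate generic number(s): %s",
                     paste(unique(annotation$generic_number[duplicated(annotation$generic_number)]),
                           collapse = ", ")))
  }
  if (anyDuplicated(annotation$position)) {
    sx_error("selexp_duplicate_generic_number",
             "multiple generic numbers assigned to the same reference position")
  }
  ref <- unclass(aln)[reference_id, ]
  nongap_cols <- which(ref != GAP)
  if (any(annotation$position < 1L) || any(annotation$position > length(nongap_cols))) {
    bad <- annotation$position[annotation$position < 1L | annotation$position > length(nongap_cols)]
    sx_error("selexp_position_out_of_range",
             sprintf("annotated position(s) %s outside reference sequence (1..%d non-gap residues)",
                     paste(bad, collapse = ", "), length(nongap_cols)))
  }
  cols <- nongap_cols[annotation$position]
  df <- data.frame(column = as.integer(cols),
                   generic_number = annotation$generic_number)
  df <- df[order_generic(df$generic_number), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("generic_number_map", "data.frame"),
            reference_id = reference_id, alignment_length = ncol(aln))
}

#' Per-column residue composition
#'
#' Counts residue occurrences per alignment column. Gaps are tallied in a
#' dedicated \code{"-"} row, so every column sums to the number of sequences.
#'
#' @param aln an \code{"aa_alignment"}.
#' @return A 21 x L integer matrix (20 amino-acid rows plus the gap row),
#'   class \code{"column_profiles"}, with attribute \code{n_sequences}.
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  lv <- c(AA20, GAP)
  m <- apply(unclass(aln), 2L, function(col) tabulate(factor(col, levels = lv), nbins = 21L))
  dimnames(m) <- list(lv, NULL)
  structure(m, class = "column_profiles", n_sequences = nrow(aln))
}

#' One-hot encode an alignment
#'
#' Each residue becomes a binary vector of length 21 (20 amino acids plus the
#' gap character), so an n x L alignment becomes an n x (21 L) matrix. Every
#' 21-channel block sums to 1 and every row sums to the alignment length.
#'
#' @param aln an \code{"aa_alignment"}.
#' @return numeric 0/1 matrix of dimension \code{n_sequences} x \code{21 * L};
#'   column names are \code{<column>_<residue>}.
#' @export
one_hot_encode <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  lv <- c(AA20, GAP)
  n <- nrow(aln); L <- ncol(aln)
  idx <- match(unclass(aln), lv)  # column-major over (seq, col)
  out <- matrix(0L, n, L * 21L)
  rows <- rep(seq_len(n), times = L)
  cols <- (rep(seq_len(L), each = n) - 1L) * 21L + idx
  out[cbind(rows, cols)] <- 1L
  colnames(out) <- paste0(rep(seq_len(L), each = 21L), "_", rep(lv, L))
  rownames(out) <- rownames(aln)
  out
}
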