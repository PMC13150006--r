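#' BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 log-odds scores for the 20 amino acids, embedded
#' as constants so that scoring needs no runtime data dependency. The matrix is
#' symmetric with non-negative diagonal entries; identity checks against the
#' copy shipped with Biostrings are part of the test suite.
#'
#' @return A symmetric 20 x 20 integer matrix with amino-acid one-letter row
#'   and column names.
#' @examples
#' m <- blosum62()
#' m["V", "S"]  # -2
#' @export
blosum62 <- function() .BLOSUM62

.BLOSUM62 <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(c(
     4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
    -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
    -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
     0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
    -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
     0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
    -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
    -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
     1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
     0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
     0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
  ), nrow = 20L, byrow = TRUE, dimnames = list(aa, aa))
  storage.mode(m) <- "integer"
  m
})

#' Look up a substitution score
#'
#' @param a,b amino-acid one-letter codes (vectorised, recycled).
#' @param matrix substitution matrix; defaults to [blosum62()].
#' @return integer vector of scores; \code{NA} where either residue is
#'   missing/\code{NA}.
#' @export
substitution_score <- function(a, b, matrix = blosum62()) {
  n <- max(length(a), length(b))
  a <- rep_len(toupper(a), n)
  b <- rep_len(toupper(b), n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(a) & !is.na(b) & a %in% rownames(matrix) & b %in% colnames(matrix)
  out[ok] <- matrix[cbind(a[ok], b[ok])]
  out
}
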