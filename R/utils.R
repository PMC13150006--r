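# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP <- "-"
AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J")

sx_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "selexp_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Parse generic residue numbers
#'
#' Splits labels of the form \code{"3x36"} (segment \code{x} position) into
#' numeric components. Three-digit positions such as \code{"5x461"} are GPCRdb
#' bulge labels and sort between the flanking two-digit positions (461 reads
#' as 46.1). Segment 45 denotes extracellular loop 2.
#'
#' @param x character vector of generic number labels.
#' @return data.frame with columns \code{segment} and \code{position} (numeric).
#' @export
parse_generic_number <- function(x) {
  ok <- grepl("^[0-9]+x[0-9]+$", x)
  if (!all(ok)) {
    sx_error("selexp_bad_generic_number",
             sprintf("malformed generic number(s): %s",
                     paste(x[!ok], collapse = ", ")))
  }
  parts <- strsplit(x, "x", fixed = TRUE)
  seg <- as.numeric(vapply(parts, `[`, "", 1L))
  pos_raw <- vapply(parts, `[`, "", 2L)
  pos <- ifelse(nchar(pos_raw) > 2L,
                as.numeric(substr(pos_raw, 1L, 2L)) +
                  as.numeric(substring(pos_raw, 3L)) / 10,
                as.numeric(pos_raw))
  data.frame(segment = seg, position = pos)
}

# Ordering permutation for generic numbers: segment first, then position.
order_generic <- function(x) {
  p <- parse_generic_number(x)
  order(p$segment, p$position)
}

# Round to two significant figures (the fold-reporting convention).
signif2 <- function(x) signif(x, 2L)

`%||%` <- function(a, b) if (is.null(a)) b else a
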