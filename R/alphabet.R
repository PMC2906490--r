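#' The extended amino-acid alphabet
#'
#' The 22-symbol alphabet used throughout the package: the 20 standard amino
#' acids in conventional one-letter code, the gap character `-`, and `X` as
#' the placeholder for any non-standard residue (B, Z, U, J, O, `*`, ...).
#' Gaps and non-standard residues take part in the column frequency counts as
#' ordinary symbols; no positions are masked or excluded.
#'
#' The position of a symbol in this vector is its integer code (1-based), and
#' encoding is a bijection between symbols and codes.
#'
#' @format character vector of length 22.
#' @examples
#' length(AA_ALPHABET_EXT)  # 22
#' @export
AA_ALPHABET_EXT <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                     "-", "X")

.GAP_CODE <- 21L
.NONSTD_CODE <- 22L

#' Encode residue characters as extended-alphabet integer codes
#'
#' Mapping is case-insensitive; both `-` and `.` are read as the gap symbol;
#' any character that is not one of the 20 standard amino acids or a gap maps
#' to the non-standard placeholder `X`.
#'
#' @param x character vector of single residue characters.
#' @return integer codes in `1:22`, indices into [AA_ALPHABET_EXT].
#' @examples
#' encodeSymbols(c("a", "C", ".", "B"))  # 1 2 21 22
#' @seealso [decodeSymbols()]
#' @export
encodeSymbols <- function(x) {
  x <- toupper(as.character(x))
  x[x == "."] <- "-"
  idx <- match(x, AA_ALPHABET_EXT)
  idx[is.na(idx)] <- .NONSTD_CODE
  idx
}

#' Decode extended-alphabet integer codes back to characters
#'
#' @param codes integer codes in `1:22`.
#' @return character vector of canonical symbols; the non-standard
#'   placeholder is rendered as `X`, the gap as `-`.
#' @seealso [encodeSymbols()]
#' @export
decodeSymbols <- function(codes) {
  codes <- as.integer(codes)
  if (any(is.na(codes)) || any(codes < 1L) || any(codes > length(AA_ALPHABET_EXT)))
    stop("symbol codes must be integers in 1:", length(AA_ALPHABET_EXT))
  AA_ALPHABET_EXT[codes]
}

# Canonicalize a raw character matrix/vector of residues (uppercase, '.'->'-',
# unknown -> 'X') without changing shape.
.canonicalizeSymbols <- function(x) {
  out <- decodeSymbols(encodeSymbols(x))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}
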