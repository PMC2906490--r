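# Entropy from a vector of symbol counts: H = log(n) - (1/n) * sum c*log(c),
# in units of log 'base'. Exact for plug-in (observed frequency) estimates,
# with 0*log(0) == 0 handled by dropping zero counts.
.entropyFromCounts <- function(counts, base = 2) {
  n <- sum(counts)
  cc <- counts[counts > 0]
  (log(n) - sum(cc * log(cc)) / n) / log(base)
}

.NSYM <- 22L

#' Shannon entropy of an alignment column
#'
#' Plug-in estimate from observed symbol frequencies over the extended
#' 22-symbol alphabet: `H = -sum_x p(x) log p(x)` with `0 log 0 = 0`. Gaps and
#' non-standard residues count as ordinary symbols.
#'
#' @param col character vector of residue symbols (one alignment column).
#' @param base logarithm base; 2 (bits, the default) or `exp(1)` (nats).
#' @return entropy in `[0, log_base(22)]`.
#' @examples
#' columnEntropy(c("A", "A", "C", "C"))  # 1 bit
#' @export
columnEntropy <- function(col, base = 2) {
  if (length(col) == 0L) stop("input error: empty column")
  .entropyFromCounts(tabulate(encodeSymbols(col), .NSYM), base)
}

#' Joint Shannon entropy of two alignment columns
#'
#' Plug-in estimate over observed symbol-pair frequencies in the 22 x 22
#' pair table.
#'
#' @param colI,colJ character vectors of equal length.
#' @inheritParams columnEntropy
#' @return joint entropy `H_ij`, satisfying
#'   `max(H_i, H_j) <= H_ij <= H_i + H_j` up to rounding.
#' @examples
#' jointEntropy(c("A", "A", "C", "C"), c("A", "C", "A", "C"))  # 2 bits
#' @export
jointEntropy <- function(colI, colJ, base = 2) {
  if (length(colI) != length(colJ))
    stop("input error: columns must have equal length (", length(colI),
         " vs ", length(colJ), ")")
  if (length(colI) == 0L) stop("input error: empty column")
  a <- encodeSymbols(colI)
  b <- encodeSymbols(colJ)
  .entropyFromCounts(tabulate((a - 1L) * .NSYM + b, .NSYM * .NSYM), base)
}

#' Mutual information between two alignment columns
#'
#' `MI = H_i + H_j - H_ij` computed from plug-in entropies. Tiny negative
#' values arising from floating-point cancellation are clamped to 0.
#'
#' @inheritParams jointEntropy
#' @return MI in `[0, min(H_i, H_j)]` (same units as the entropies).
#' @examples
#' mutualInformation(c("A", "A", "C", "C"), c("A", "A", "C", "C"))  # 1
#' mutualInformation(c("A", "A", "C", "C"), c("A", "C", "A", "C"))  # 0
#' @export
mutualInformation <- function(colI, colJ, base = 2) {
  mi <- columnEntropy(colI, base) + columnEntropy(colJ, base) -
    jointEntropy(colI, colJ, base)
  max(mi, 0)
}

# MI matrix from an integer-coded alignment (n x L codes in 1..22).
# Diagonal holds the column entropies; off-diagonal values are clamped at 0
# and mirrored so the matrix is exactly symmetric.
.miMatrixCodes <- function(codes, base = 2) {
  L <- ncol(codes)
  counts <- lapply(seq_len(L), function(j) tabulate(codes[, j], .NSYM))
  H <- vapply(counts, .entropyFromCounts, numeric(1), base = base)
  m <- diag(H, nrow = L)
  if (L > 1L) {
    shifted <- (codes - 1L) * .NSYM
    for (i in seq_len(L - 1L)) {
      si <- shifted[, i]
      for (j in (i + 1L):L) {
        hij <- .entropyFromCounts(tabulate(si + codes[, j], .NSYM * .NSYM),
                                  base)
        m[i, j] <- m[j, i] <- max(H[i] + H[j] - hij, 0)
      }
    }
  }
  m
}

#' Mutual information matrix of an alignment
#'
#' Computes all `L(L+1)/2` unique values once and mirrors them into a
#' symmetric `L x L` matrix. The diagonal holds the column entropies `H_i`
#' (the self-pair `MI_ii = H_i`).
#'
#' @param aln an [MsaAlignment-class] object.
#' @inheritParams columnEntropy
#' @return symmetric numeric matrix, in the units of `base`.
#' @examples
#' aln <- MsaAlignment(c("AAC", "ACC", "CAA", "CCA"))
#' miMatrix(aln)
#' @seealso [sampleNull()], [zScores()]
#' @export
miMatrix <- function(aln, base = 2) {
  stopifnot(is(aln, "MsaAlignment"))
  .miMatrixCodes(.alignmentCodes(aln), base = base)
}

#' Number of unique column pairs, self-pairs included
#'
#' For `L` alignment columns there are `L(L+1)/2` unordered pairs `(i, j)`
#' with `i <= j` (e.g. 5050 for `L = 100`).
#'
#' @param L column count, `>= 1`.
#' @return integer-valued count.
#' @examples
#' pairCount(100)  # 5050
#' @export
pairCount <- function(L) {
  L <- as.numeric(L)
  if (length(L) != 1L || is.na(L) || L < 1 || L != floor(L))
    stop("input error: 'L' must be a single integer >= 1")
  L * (L + 1) / 2
}
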