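#' @import methods
NULL

#' Multiple sequence alignment over the extended amino-acid alphabet
#'
#' An `MsaAlignment` holds an aligned set of protein sequences as a character
#' matrix of canonical symbols (rows = sequences, columns = alignment
#' positions). Every symbol belongs to the extended 22-letter alphabet
#' [AA_ALPHABET_EXT]: the 20 standard amino acids, `-` for gaps and `X` for
#' non-standard residues. Columns of this matrix are the random variables
#' whose pairwise mutual information is analysed.
#'
#' @slot ids character vector of sequence identifiers (record order).
#' @slot seqs character matrix, `nSequences x nColumns`, canonical symbols.
#'
#' @seealso [readFastaAlignment()], [generateAlignment()], [miMatrix()]
#' @export
setClass("MsaAlignment",
  representation(ids = "character", seqs = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.character(object@seqs))
      msg <- c(msg, "'seqs' must be a character matrix")
    if (nrow(object@seqs) < 2L)
      msg <- c(msg, "an alignment needs at least 2 sequences")
    if (ncol(object@seqs) < 1L)
      msg <- c(msg, "an alignment needs at least 1 column")
    if (length(object@ids) != nrow(object@seqs))
      msg <- c(msg, "'ids' length must equal the number of sequences")
    if (is.character(object@seqs) &&
        !all(object@seqs %in% AA_ALPHABET_EXT))
      msg <- c(msg, "all symbols must belong to AA_ALPHABET_EXT")
    if (length(msg)) msg else TRUE
  }
)

#' Column-shuffle null model statistics
#'
#' Per-pair sample mean and standard deviation of the mutual information over
#' independent column-shuffle replicates. Shuffling permutes each column's
#' entries across sequences, preserving every single-column entropy while
#' destroying inter-column correlation; the resulting per-pair distribution is
#' the neutral-evolution reference against which observed MI values are
#' standardised to Z-scores.
#'
#' @slot mean L x L matrix, per-pair mean MI over replicates.
#' @slot sd L x L matrix, per-pair sample standard deviation (n-1 denominator).
#' @slot nReplicates number of shuffle replicates.
#' @slot seed RNG seed used.
#' @slot base logarithm base of the entropy unit (2 = bits).
#'
#' @seealso [sampleNull()], [zScores()]
#' @export
setClass("ShuffleNull",
  representation(mean = "matrix", sd = "matrix", nReplicates = "integer",
                 seed = "integer", base = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mean), dim(object@sd)))
      msg <- c(msg, "'mean' and 'sd' must have identical dimensions")
    if (nrow(object@mean) != ncol(object@mean))
      msg <- c(msg, "null statistics must be square matrices")
    if (any(object@sd < 0, na.rm = TRUE))
      msg <- c(msg, "'sd' must be non-negative")
    if (object@nReplicates < 2L)
      msg <- c(msg, "'nReplicates' must be at least 2")
    if (length(msg)) msg else TRUE
  }
)

#' Result of greedy seed-row / L1 matrix seriation
#'
#' Row and column permutations produced by the greedy seriation pass
#' ([sortMatrix()]) together with the reordered matrix, so that
#' `sortedMatrix(x)[a, b] == original[rowOrder(x)[a], colOrder(x)[b]]`.
#' Keeping the permutations preserves the mapping back to original alignment
#' positions for labelling.
#'
#' @slot rowOrder integer permutation of `1:nrow`.
#' @slot colOrder integer permutation of `1:ncol`.
#' @slot sortedMatrix the reordered matrix.
#'
#' @seealso [sortMatrix()], [sortRows()]
#' @export
setClass("SortResult",
  representation(rowOrder = "integer", colOrder = "integer",
                 sortedMatrix = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(sort(object@rowOrder), seq_len(nrow(object@sortedMatrix))))
      msg <- c(msg, "'rowOrder' must be a permutation of row indices")
    if (!identical(sort(object@colOrder), seq_len(ncol(object@sortedMatrix))))
      msg <- c(msg, "'colOrder' must be a permutation of column indices")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "MsaAlignment", function(object) {
  cat("MsaAlignment:", nrow(object@seqs), "sequences x",
      ncol(object@seqs), "columns\n")
  n <- min(3L, nrow(object@seqs))
  for (k in seq_len(n)) {
    s <- paste(object@seqs[k, seq_len(min(40L, ncol(object@seqs)))],
               collapse = "")
    if (ncol(object@seqs) > 40L) s <- paste0(s, "...")
    cat(sprintf("  %-12s %s\n", substr(object@ids[k], 1L, 12L), s))
  }
  if (nrow(object@seqs) > n) cat("  ...\n")
})

setMethod("show", "ShuffleNull", function(object) {
  cat("ShuffleNull:", nrow(object@mean), "x", ncol(object@mean),
      "pair statistics over", object@nReplicates, "shuffle replicates",
      sprintf("(seed %d, log base %g)\n", object@seed, object@base))
  cat(sprintf("  mean MI range: [%.4g, %.4g]\n",
              min(object@mean), max(object@mean)))
  cat(sprintf("  sd range:      [%.4g, %.4g]\n",
              min(object@sd), max(object@sd)))
})

setMethod("show", "SortResult", function(object) {
  cat("SortResult:", nrow(object@sortedMatrix), "x",
      ncol(object@sortedMatrix), "matrix\n")
  cat("  rowOrder:", paste(utils::head(object@rowOrder, 10L), collapse = " "),
      if (length(object@rowOrder) > 10L) "...\n" else "\n")
  cat("  colOrder:", paste(utils::head(object@colOrder, 10L), collapse = " "),
      if (length(object@colOrder) > 10L) "...\n" else "\n")
})
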