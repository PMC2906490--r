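#' Shuffle one alignment column
#'
#' Returns a uniform random permutation of the column's entries (drawn with
#' [sample()] from R's current RNG stream). The symbol multiset — and hence
#' the column entropy — is conserved exactly; only the pairing with other
#' columns is destroyed.
#'
#' @param col symbol vector (any type).
#' @return a permutation of `col`.
#' @examples
#' set.seed(1)
#' sort(shuffleColumn(c("A", "C", "D"))) # "A" "C" "D"
#' @export
shuffleColumn <- function(col) {
  if (length(col) == 0L) stop("input error: empty column")
  col[sample.int(length(col))]
}

#' Sample the column-shuffle null model
#'
#' For each replicate every alignment column is independently re-permuted
#' across sequences and the full MI matrix is recomputed. Because a shuffle
#' conserves each column's symbol multiset, every single-column entropy is
#' bit-identical to the original in every replicate; any MI in excess of the
#' resulting null distribution reflects inter-column correlation rather than
#' finite-sample bias. The per-pair sample mean and standard deviation
#' (`n - 1` denominator) over replicates are returned as a
#' [ShuffleNull-class] object.
#'
#' Results are deterministic: identical (alignment, `nReplicates`, `seed`)
#' give bit-identical statistics.
#'
#' @param aln an [MsaAlignment-class] object.
#' @param nReplicates number of shuffle replicates, `>= 2` (default 100).
#' @param seed integer RNG seed.
#' @param base logarithm base of the entropies (2 = bits).
#' @return a [ShuffleNull-class] object.
#' @examples
#' aln <- generateAlignment(20, 4, seed = 7)
#' null <- sampleNull(aln, nReplicates = 25, seed = 7)
#' @seealso [zScores()]
#' @export
sampleNull <- function(aln, nReplicates = 100L, seed = 1L, base = 2) {
  stopifnot(is(aln, "MsaAlignment"))
  nReplicates <- as.integer(nReplicates)
  if (is.na(nReplicates) || nReplicates < 2L)
    stop("input error: 'nReplicates' must be >= 2 ",
         "(the sample standard deviation is undefined otherwise)")
  codes <- .alignmentCodes(aln)
  n <- nrow(codes)
  L <- ncol(codes)
  # Welford's online mean/M2 update: cancellation-free, so pairs whose MI is
  # shuffle-invariant (e.g. the diagonal entropies) get an exact sd of 0.
  mu <- matrix(0, L, L)
  m2 <- matrix(0, L, L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (r in seq_len(nReplicates)) {
    shuf <- codes
    for (j in seq_len(L)) shuf[, j] <- codes[sample.int(n), j]
    m <- .miMatrixCodes(shuf, base = base)
    delta <- m - mu
    mu <- mu + delta / r
    m2 <- m2 + delta * (m - mu)
  }
  v <- m2 / (nReplicates - 1)
  new("ShuffleNull", mean = mu, sd = sqrt(v),
      nReplicates = nReplicates, seed = as.integer(seed), base = base)
}

#' ShuffleNull accessors
#'
#' @param x a [ShuffleNull-class] object.
#' @return `nullMean`/`nullSd`: the per-pair statistic matrices;
#'   `nReplicates`: the replicate count.
#' @name ShuffleNull-accessors
#' @aliases nullMean nullSd nReplicates
NULL

#' @rdname ShuffleNull-accessors
#' @export
setMethod("nullMean", "ShuffleNull", function(x) x@mean)

#' @rdname ShuffleNull-accessors
#' @export
setMethod("nullSd", "ShuffleNull", function(x) x@sd)

#' @rdname ShuffleNull-accessors
#' @export
setMethod("nReplicates", "ShuffleNull", function(x) x@nReplicates)

#' Z-scores of observed MI against the shuffle null
#'
#' `Z_ij = (MI_ij - <MI_ij>) / sigma(MI_ij)` per pair. Pairs whose null
#' standard deviation is zero (e.g. invariant columns, which shuffling cannot
#' change) are undefined and returned as `NA` rather than infinity; exports
#' omit them and rendering gives them zero weight. The Z-score is invariant
#' under a change of entropy log base, since MI, mean and standard deviation
#' all scale by the same factor.
#'
#' @param mi observed MI matrix, as from [miMatrix()].
#' @param null a [ShuffleNull-class] object with matching dimensions.
#' @return numeric matrix of Z-scores with `NA` where the null sd is 0.
#' @examples
#' aln <- generateAlignment(30, 5, seed = 3)
#' z <- zScores(miMatrix(aln), sampleNull(aln, 20, seed = 3))
#' @export
zScores <- function(mi, null) {
  stopifnot(is.matrix(mi), is(null, "ShuffleNull"))
  if (!identical(dim(mi), dim(null@mean)))
    stop("input error: MI matrix is ", nrow(mi), "x", ncol(mi),
         " but null statistics are ", nrow(null@mean), "x", ncol(null@mean))
  z <- (mi - null@mean) / null@sd
  z[null@sd == 0] <- NA_real_
  z
}
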