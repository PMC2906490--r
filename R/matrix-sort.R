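#' Find the seed row of a matrix
#'
#' The seed row is the row with the maximal sum of contained values; it is the
#' starting point of the greedy seriation chain. Masked (`NA`) cells
#' contribute 0 to the sums; ties are broken by the lowest row index.
#'
#' @param m numeric matrix.
#' @return 1-based row index.
#' @examples
#' findSeedRow(rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5)))  # 3
#' @export
findSeedRow <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("input error: empty matrix")
  m[is.na(m)] <- 0
  which.max(rowSums(m))  # which.max returns the first (lowest-index) maximum
}

#' L1 distance between two value vectors
#'
#' Sum of absolute componentwise differences; positions where either entry is
#' masked (`NA`) contribute 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @examples
#' l1Distance(c(1, 2, 3), c(5, 5, 5))  # 9
#' @export
l1Distance <- function(a, b) {
  if (length(a) != length(b))
    stop("input error: vectors must have equal length (", length(a),
         " vs ", length(b), ")")
  d <- abs(a - b)
  sum(d[!is.na(d)])
}

#' Greedy seed-row ordering of matrix rows
#'
#' The seed row (maximal value sum) is placed first; each subsequent position
#' takes the not-yet-placed row with the smallest L1 distance to the
#' previously placed row, ties broken by lowest original index. The chain
#' continues until all rows are placed, so similar rows end up adjacent.
#' Quadratic time in the number of rows.
#'
#' @param m numeric matrix; `NA` cells count as 0 in sums and distances.
#' @return integer permutation of `1:nrow(m)`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5))
#' sortRows(m)  # 3 1 2
#' @seealso [sortMatrix()]
#' @export
sortRows <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("input error: empty matrix")
  m[is.na(m)] <- 0
  L <- nrow(m)
  ord <- integer(L)
  ord[1L] <- findSeedRow(m)
  remaining <- setdiff(seq_len(L), ord[1L])
  for (k in seq_len(L - 1L)) {
    prev <- m[ord[k], ]
    d <- vapply(remaining, function(r) sum(abs(prev - m[r, ])), numeric(1))
    pick <- remaining[which.min(d)]  # first minimum = lowest original index
    ord[k + 1L] <- pick
    remaining <- remaining[remaining != pick]
  }
  ord
}

#' Seriation of a matrix by greedy seed-row / L1 chaining
#'
#' Applies [sortRows()] to the rows of the matrix, then the same procedure to
#' the columns of the row-reordered matrix (the two passes are sequential and
#' independent; for a symmetric matrix they may yield different row and
#' column orders). Both permutations are recorded so original alignment
#' positions survive for labelling.
#'
#' @param m numeric matrix.
#' @return a [SortResult-class] object.
#' @examples
#' sr <- sortMatrix(rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5)))
#' rowOrder(sr)  # 3 1 2
#' @export
sortMatrix <- function(m) {
  stopifnot(is.matrix(m))
  ro <- sortRows(m)
  m2 <- m[ro, , drop = FALSE]
  co <- sortRows(t(m2))
  new("SortResult", rowOrder = as.integer(ro), colOrder = as.integer(co),
      sortedMatrix = m2[, co, drop = FALSE])
}

#' SortResult accessors
#'
#' @param x a [SortResult-class] object.
#' @return `rowOrder`/`colOrder`: integer permutations mapping display
#'   position to original index; `sortedMatrix`: the reordered matrix.
#' @name SortResult-accessors
#' @aliases rowOrder colOrder sortedMatrix
NULL

#' @rdname SortResult-accessors
#' @export
setMethod("rowOrder", "SortResult", function(x) x@rowOrder)

#' @rdname SortResult-accessors
#' @export
setMethod("colOrder", "SortResult", function(x) x@colOrder)

#' @rdname SortResult-accessors
#' @export
setMethod("sortedMatrix", "SortResult", function(x) x@sortedMatrix)
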