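#' Range filter on MI and Z matrices
#'
#' Builds a logical mask that is `TRUE` where the MI value lies inside
#' `miRange` and, when `zRange` is given, the Z-score lies inside `zRange`.
#' All bounds are inclusive, so exact threshold hits survive. Cells whose Z is
#' undefined (`NA`) fail any Z-bounded filter; `NA` MI cells always fail.
#' Filtering never mutates values — downstream sorting, rendering and export
#' all accept the mask.
#'
#' @param mi numeric MI matrix.
#' @param z optional numeric Z matrix (required if `zRange` is given).
#' @param miRange length-2 numeric `c(lo, hi)`; use `-Inf`/`Inf` for an
#'   unbounded side.
#' @param zRange optional length-2 numeric `c(lo, hi)`.
#' @return logical matrix of the same dimensions.
#' @examples
#' mi <- rbind(c(1.0, 0.2), c(0.2, 0.8))
#' applyFilter(mi, miRange = c(0.5, Inf))
#' @export
applyFilter <- function(mi, z = NULL, miRange = c(-Inf, Inf), zRange = NULL) {
  stopifnot(is.matrix(mi))
  .checkRange(miRange, "miRange")
  mask <- !is.na(mi) & mi >= miRange[1L] & mi <= miRange[2L]
  if (!is.null(zRange)) {
    .checkRange(zRange, "zRange")
    if (is.null(z))
      stop("input error: Z bounds given but no Z matrix supplied")
    if (!identical(dim(z), dim(mi)))
      stop("input error: Z matrix dimensions do not match the MI matrix")
    mask <- mask & !is.na(z) & z >= zRange[1L] & z <= zRange[2L]
  }
  mask
}

.checkRange <- function(r, what) {
  if (length(r) != 2L || any(is.na(r)))
    stop("input error: '", what, "' must be c(lo, hi)")
  if (r[1L] > r[2L])
    stop("input error: '", what, "' has lo > hi (", r[1L], " > ", r[2L], ")")
  invisible(r)
}

#' Combine a data and a weight matrix by multiplication
#'
#' Elementwise product of the two matrices; a cell undefined (`NA`) in either
#' operand is undefined in the result.
#'
#' @param data,weight numeric matrices of equal dimensions.
#' @return numeric matrix.
#' @examples
#' combineMultiply(rbind(c(2, 3)), rbind(c(0.5, 0)))  # 1 0
#' @export
combineMultiply <- function(data, weight) {
  stopifnot(is.matrix(data), is.matrix(weight))
  if (!identical(dim(data), dim(weight)))
    stop("input error: data is ", nrow(data), "x", ncol(data),
         " but weight is ", nrow(weight), "x", ncol(weight))
  data * weight
}

#' Saturation weights from Z-scores
#'
#' Linear ramp `w = clamp((Z - zLo) / (zHi - zLo), 0, 1)` mapping Z-scores to
#' color-saturation weights: cells at or below `zLo` are fully washed out
#' (weight 0), cells at or above `zHi` fully saturated (weight 1). Undefined
#' (`NA`) Z cells get weight 0.
#'
#' @param z numeric Z matrix.
#' @param zLo,zHi ramp bounds, `zLo < zHi`.
#' @return numeric matrix with values in `[0, 1]`.
#' @examples
#' saturationWeights(rbind(c(0, 2, 4)), zLo = 0, zHi = 4)  # 0 0.5 1
#' @export
saturationWeights <- function(z, zLo, zHi) {
  stopifnot(is.matrix(z))
  if (!(zLo < zHi))
    stop("input error: 'zLo' must be strictly below 'zHi'")
  w <- (z - zLo) / (zHi - zLo)
  w[w < 0] <- 0
  w[w > 1] <- 1
  w[is.na(w)] <- 0
  w
}

#' Export the cells selected by a mask
#'
#' Writes exactly the cells where `mask` is `TRUE` in the triple-per-line
#' format, with original 1-based position labels. An all-`FALSE` mask yields
#' a file containing only the comment header.
#'
#' @param m numeric matrix.
#' @param mask logical matrix of the same dimensions.
#' @param path output file path.
#' @param rowLabels,colLabels optional original position labels.
#' @return the path, invisibly.
#' @seealso [applyFilter()], [writeMatrixTriples()]
#' @export
exportSelection <- function(m, mask, path, rowLabels = NULL,
                            colLabels = NULL) {
  stopifnot(is.matrix(m), is.logical(mask))
  if (!identical(dim(m), dim(mask)))
    stop("input error: mask dimensions do not match the matrix")
  sel <- m
  sel[!mask] <- NA_real_
  writeMatrixTriples(sel, path, rowLabels = rowLabels, colLabels = colLabels)
}
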