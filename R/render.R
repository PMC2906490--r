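.COLOR_SCALES <- list(
  sequential = list(colors = c("#FFFFFF", "#08306B"),
                    background = c(0.85, 0.85, 0.85)),
  diverging  = list(colors = c("#2166AC", "#F7F7F7", "#B2182B"),
                    background = c(0.85, 0.85, 0.85)),
  grey       = list(colors = c("#FFFFFF", "#000000"),
                    background = c(1, 0.9, 0.9))
)

#' Available color scale names
#'
#' A sequential single-hue scale (white to dark blue; default for MI), a
#' diverging blue-white-red scale (suited to Z-scores centred on 0) and a
#' greyscale. Masked cells are painted in the scale's background color.
#'
#' @return character vector of scale names.
#' @export
colorScaleNames <- function() names(.COLOR_SCALES)

#' Look up a color scale
#'
#' @param name one of [colorScaleNames()].
#' @return list with `map`, a function from normalized values in `[0, 1]` to
#'   an `n x 3` RGB matrix in `[0, 1]`, and `background`, the RGB triple for
#'   masked cells.
#' @examples
#' sc <- getColorScale("sequential")
#' sc$map(c(0, 1))
#' @export
getColorScale <- function(name) {
  if (!name %in% names(.COLOR_SCALES))
    stop("input error: unknown color scale '", name, "'; available: ",
         paste(names(.COLOR_SCALES), collapse = ", "))
  spec <- .COLOR_SCALES[[name]]
  ramp <- grDevices::colorRamp(spec$colors, space = "rgb")
  list(name = name,
       map = function(v) ramp(v) / 255,
       background = spec$background)
}

#' Normalize matrix values to [0, 1]
#'
#' Under `"minmax"` the observed minimum maps to 0 and the maximum to 1; a
#' constant matrix maps to all 0.5 by convention. Under `"fixed"` the given
#' `range` is used and values outside it are clamped. Masked (`NA`) cells
#' stay masked.
#'
#' @param m numeric matrix with at least one unmasked finite cell.
#' @param mode `"minmax"` (default) or `"fixed"`.
#' @param range length-2 numeric, required for `mode = "fixed"`.
#' @return numeric matrix in `[0, 1]` with `NA` preserved.
#' @examples
#' normalizeValues(rbind(c(0, 5), c(10, 5)))
#' @export
normalizeValues <- function(m, mode = c("minmax", "fixed"), range = NULL) {
  stopifnot(is.matrix(m))
  mode <- match.arg(mode)
  vals <- m[!is.na(m)]
  if (length(vals) == 0L)
    stop("input error: matrix has no unmasked cells to normalize")
  if (mode == "minmax") {
    lo <- min(vals); hi <- max(vals)
    if (hi == lo) {
      out <- m
      out[!is.na(out)] <- 0.5
      return(out)
    }
  } else {
    .checkRange(range, "range")
    lo <- range[1L]; hi <- range[2L]
    if (hi == lo) stop("input error: fixed range has zero width")
  }
  out <- (m - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Render a normalized matrix as an RGB heatmap image
#'
#' Each cell becomes a `cellPx x cellPx` block of identical pixels
#' (`cellPx = 1` gives one pixel per pairwise relationship). Masked cells are
#' painted in the scale's background color; an optional saturation weight
#' matrix `sat` in `[0, 1]` blends each cell's color linearly from the
#' background (weight 0) to the full scale color (weight 1). Channel values
#' are quantized to 8 bits here, so PNG export is lossless and
#' byte-deterministic.
#'
#' @param m numeric matrix with values in `[0, 1]` (see [normalizeValues()]).
#' @param scale a color scale from [getColorScale()], or its name.
#' @param mask optional logical matrix; cells where it is `FALSE` are painted
#'   background.
#' @param sat optional numeric weight matrix in `[0, 1]`.
#' @param cellPx integer pixels per cell, `>= 1`.
#' @return numeric array `(nrow*cellPx) x (ncol*cellPx) x 3` in `[0, 1]`.
#' @examples
#' img <- renderMatrix(normalizeValues(diag(4)), "sequential", cellPx = 2)
#' dim(img)  # 8 8 3
#' @seealso [exportPNG()]
#' @export
renderMatrix <- function(m, scale = "sequential", mask = NULL, sat = NULL,
                         cellPx = 1L) {
  stopifnot(is.matrix(m))
  cellPx <- as.integer(cellPx)
  if (is.na(cellPx) || cellPx < 1L)
    stop("input error: 'cellPx' must be an integer >= 1")
  if (is.character(scale)) scale <- getColorScale(scale)
  shown <- !is.na(m)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(m)))
      stop("input error: mask dimensions do not match the matrix")
    shown <- shown & mask
  }
  v <- ifelse(shown, m, 0)
  if (any(v < 0 | v > 1))
    stop("input error: matrix must be normalized to [0, 1] before rendering")
  rgb <- scale$map(as.vector(v))          # (nrow*ncol) x 3, column-major cells
  bg <- scale$background
  if (!is.null(sat)) {
    if (!identical(dim(sat), dim(m)))
      stop("input error: saturation matrix dimensions do not match")
    w <- as.vector(sat)
    w[is.na(w)] <- 0
    rgb <- rep(bg, each = nrow(rgb)) + w * sweep(rgb, 2L, bg)
  }
  hide <- !as.vector(shown)
  rgb[hide, ] <- rep(bg, each = sum(hide))
  rgb <- round(rgb * 255) / 255  # 8-bit quantization for lossless PNG export
  img <- array(0, c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], nrow(m), ncol(m))
  if (cellPx > 1L) {
    img <- img[rep(seq_len(nrow(m)), each = cellPx),
               rep(seq_len(ncol(m)), each = cellPx), , drop = FALSE]
  }
  img
}

#' Export an RGB image as a lossless PNG
#'
#' Writes 8-bit-per-channel RGB PNG. Decoding the written file reproduces the
#' pixel values exactly, and identical images give byte-identical files.
#'
#' @param img numeric array `h x w x 3` with values in `[0, 1]`.
#' @param path output path.
#' @param overwrite set `TRUE` to allow replacing an existing file.
#' @return the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' exportPNG(renderMatrix(normalizeValues(diag(3))), f)
#' @export
exportPNG <- function(img, path, overwrite = FALSE) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3L] == 3L)
  if (file.exists(path) && !overwrite)
    stop("io error: '", path, "' exists; use overwrite = TRUE to replace it")
  ok <- tryCatch({ png::writePNG(img, target = path); TRUE },
                 error = function(e) stop("io error: cannot write '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  invisible(path)
}

#' Histogram of matrix values
#'
#' Equal-width bins over the observed range of the unmasked cells. For a
#' symmetric matrix, set `uniquePairs = TRUE` to count each unordered pair
#' (`i <= j`, self-pairs included) once instead of twice.
#'
#' @param m numeric matrix.
#' @param nBins number of bins, `>= 1`.
#' @param mask optional logical matrix; only cells where it is `TRUE` count.
#' @param uniquePairs logical; restrict to the upper triangle incl. diagonal.
#' @return list with `breaks` (length `nBins + 1`) and `counts` (length
#'   `nBins`); counts sum to the number of unmasked cells considered.
#' @examples
#' valueHistogram(rbind(c(1, 2), c(3, 4)), nBins = 2)
#' @export
valueHistogram <- function(m, nBins, mask = NULL, uniquePairs = FALSE) {
  stopifnot(is.matrix(m))
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 1L)
    stop("input error: 'nBins' must be >= 1")
  keep <- !is.na(m)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(m)))
      stop("input error: mask dimensions do not match the matrix")
    keep <- keep & mask
  }
  if (uniquePairs) {
    if (nrow(m) != ncol(m))
      stop("input error: 'uniquePairs' needs a square matrix")
    keep <- keep & upper.tri(m, diag = TRUE)
  }
  vals <- m[keep]
  if (length(vals) == 0L)
    stop("input error: no unmasked cells to histogram")
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) hi <- lo + 1  # all-equal values fall into the first bin
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  list(breaks = breaks, counts = tabulate(idx, nBins))
}
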