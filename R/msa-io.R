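#' Construct an MsaAlignment from raw sequences
#'
#' Residues are canonicalized through the extended alphabet (case-insensitive;
#' `.` and `-` both become the gap symbol; anything outside the 20 standard
#' amino acids becomes `X`).
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix of single residues (rows = sequences).
#' @param ids sequence identifiers; defaults to `seq1, seq2, ...`.
#' @return an [MsaAlignment-class] object.
#' @examples
#' MsaAlignment(c("ACD-", "ACDE"))
#' @export
MsaAlignment <- function(seqs, ids = NULL) {
  if (!is.matrix(seqs)) {
    seqs <- as.character(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("aligned sequences must all have the same length")
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  new("MsaAlignment", ids = as.character(ids),
      seqs = .canonicalizeSymbols(seqs))
}

#' Read a FASTA multiple sequence alignment
#'
#' Reads a standard (possibly multi-line) FASTA file and encodes every residue
#' through the extended alphabet. The file must contain at least two records
#' of identical length; record order defines sequence identity, and duplicate
#' identifiers are permitted with a warning.
#'
#' @param path path to a FASTA file.
#' @return an [MsaAlignment-class] object.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACD", ">b", "AC-"), fa)
#' aln <- readFastaAlignment(fa)
#' nColumns(aln)  # 3
#' @seealso [writeFastaAlignment()]
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e)
                   stop("parse error: malformed FASTA in '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (length(ss) < 2L)
    stop("input error: alignment must contain at least 2 FASTA records (found ",
         length(ss), ")")
  w <- Biostrings::width(ss)
  if (any(w == 0L))
    stop("input error: empty sequence record '", names(ss)[w == 0L][1L], "'")
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop("alignment error: record '", names(ss)[bad], "' has length ", w[bad],
         " but record '", names(ss)[1L], "' has length ", w[1L])
  }
  ids <- names(ss)
  if (is.null(ids)) ids <- paste0("seq", seq_along(ss))
  if (anyDuplicated(ids))
    warning("duplicate FASTA identifiers; records are kept in file order")
  MsaAlignment(as.character(ss), ids = ids)
}

#' Write an alignment as FASTA
#'
#' @param aln an [MsaAlignment-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(is(aln, "MsaAlignment"))
  ss <- Biostrings::BStringSet(apply(aln@seqs, 1L, paste, collapse = ""))
  names(ss) <- aln@ids
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta")
  invisible(path)
}

#' Alignment dimensions and identifiers
#'
#' @param x an [MsaAlignment-class] object.
#' @return `nSequences`/`nColumns`: integer counts; `seqIds`: character
#'   identifiers; `alignmentMatrix`: the character matrix of canonical
#'   symbols.
#' @name MsaAlignment-accessors
#' @aliases nSequences nColumns seqIds alignmentMatrix
NULL

#' @rdname MsaAlignment-accessors
#' @export
setMethod("nSequences", "MsaAlignment", function(x) nrow(x@seqs))

#' @rdname MsaAlignment-accessors
#' @export
setMethod("nColumns", "MsaAlignment", function(x) ncol(x@seqs))

#' @rdname MsaAlignment-accessors
#' @export
setMethod("seqIds", "MsaAlignment", function(x) x@ids)

#' @rdname MsaAlignment-accessors
#' @export
setMethod("alignmentMatrix", "MsaAlignment", function(x) x@seqs)

#' Extract one alignment column
#'
#' @param x an [MsaAlignment-class] object.
#' @param j 1-based alignment position.
#' @return character vector of length `nSequences(x)`, top-to-bottom in
#'   record order.
#' @name getColumn
#' @examples
#' aln <- MsaAlignment(c("AC", "GC"))
#' getColumn(aln, 2)  # "C" "C"
#' @export
setMethod("getColumn", "MsaAlignment", function(x, j) {
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > ncol(x@seqs))
    stop("index error: column index ", j, " out of range 1..", ncol(x@seqs))
  x@seqs[, j]
})

# integer-coded alignment (n x L matrix of codes 1..22) for fast counting
.alignmentCodes <- function(aln) {
  codes <- encodeSymbols(aln@seqs)
  dim(codes) <- dim(aln@seqs)
  codes
}

#' Write a matrix in the triple-per-line plain-text format
#'
#' One line per stored cell, `row column value` with single spaces, 1-based
#' indices, deterministic row-major order. Cells that are `NA` (masked /
#' undefined) are omitted. Values are printed with 17 significant digits so a
#' write-read round trip reproduces doubles exactly. A `# row column value`
#' comment header is always written; readers ignore `#` lines.
#'
#' @param m numeric matrix; `NA` cells are skipped.
#' @param path output file path.
#' @param rowLabels,colLabels optional 1-based original position labels (used
#'   to preserve residue numbering after sorting or sub-setting); default
#'   `1:nrow`, `1:ncol`.
#' @return the path, invisibly.
#' @seealso [readMatrixTriples()]
#' @export
writeMatrixTriples <- function(m, path, rowLabels = NULL, colLabels = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(rowLabels)) rowLabels <- seq_len(nrow(m))
  if (is.null(colLabels)) colLabels <- seq_len(ncol(m))
  keep <- which(!is.na(t(m)))  # transpose -> row-major enumeration
  jj <- ((keep - 1L) %% ncol(m)) + 1L
  ii <- ((keep - 1L) %/% ncol(m)) + 1L
  vals <- t(m)[keep]
  lines <- c("# row column value",
             sprintf("%d %d %.17g", rowLabels[ii], colLabels[jj], vals))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("io error: cannot write '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a matrix from the triple-per-line plain-text format
#'
#' Each non-blank, non-comment line must parse as `row column value`;
#' whitespace and comma separators are both accepted. The matrix extent is
#' inferred from the largest indices; cells absent from the file are `NA`
#' (missing). No symmetric completion is applied: only stored cells are
#' filled.
#'
#' @param path input file path.
#' @return numeric matrix with `NA` in unstored cells.
#' @seealso [writeMatrixTriples()]
#' @export
readMatrixTriples <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  fields <- strsplit(trimws(raw[keep]), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("parse error at line ", keep[which(nf != 3L)[1L]],
         ": expected 'row column value'")
  toNum <- function(k) suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
  ri <- toNum(1L); ci <- toNum(2L); vv <- toNum(3L)
  bad <- which(is.na(ri) | is.na(ci) | is.na(vv) |
                 ri != floor(ri) | ci != floor(ci) | ri < 1 | ci < 1)
  if (length(bad))
    stop("parse error at line ", keep[bad[1L]],
         ": indices must be positive integers and value numeric")
  key <- paste(ri, ci)
  if (anyDuplicated(key))
    stop("input error: duplicate cell (",
         key[duplicated(key)][1L], ") in '", path, "'")
  m <- matrix(NA_real_, nrow = max(ri), ncol = max(ci))
  m[cbind(ri, ci)] <- vv
  m
}
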