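#' Specify a planted coupled column pair
#'
#' Coupling is modeled as probabilistic bijective relabeling: with probability
#' `coupling` a sequence's symbol at position `j` is a fixed bijective image
#' of its symbol at position `i`; otherwise it is drawn independently from the
#' background distribution. `coupling = 1` makes column `j` a deterministic
#' relabeling of column `i` (so their MI equals the column entropy);
#' `coupling = 0` makes the columns independent by construction. The
#' mechanism is the simplest one that gives a closed-form joint distribution
#' for oracle tests; it makes no claim of biological realism.
#'
#' @param i,j distinct 1-based alignment positions.
#' @param coupling real in `[0, 1]`.
#' @return a `CouplingSpec` list.
#' @seealso [generateAlignment()], [expectedMI()]
#' @export
couplingSpec <- function(i, j, coupling) {
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i == j)
    stop("input error: coupled positions must be distinct positive integers")
  if (is.na(coupling) || coupling < 0 || coupling > 1)
    stop("input error: 'coupling' must lie in [0, 1]")
  structure(list(i = i, j = j, coupling = coupling), class = "CouplingSpec")
}

# fixed bijection used for relabeling: cyclic shift of the background symbols
.couplingMap <- function(symbols) {
  stats::setNames(symbols[c(seq_along(symbols)[-1L], 1L)], symbols)
}

#' Generate a synthetic alignment with optional planted coupled pairs
#'
#' Uncoupled columns are filled i.i.d. from the background symbol
#' distribution; each [couplingSpec()] pair follows the probabilistic
#' relabeling model. The default background is uniform over a reduced
#' 4-symbol alphabet (A, C, G, T — all valid amino-acid codes), which gives
#' fast, high-entropy columns; any distribution over the extended alphabet is
#' accepted. Output is deterministic under `seed` and writable as FASTA.
#'
#' @param nSeqs number of sequences, `>= 2`.
#' @param nCols number of alignment columns.
#' @param background named numeric vector of symbol probabilities (sums
#'   to 1); names must be extended-alphabet symbols.
#' @param couplings list of [couplingSpec()] objects; coupled positions must
#'   not overlap between specs.
#' @param seed integer RNG seed.
#' @return an [MsaAlignment-class] object.
#' @examples
#' aln <- generateAlignment(50, 10,
#'                          couplings = list(couplingSpec(2, 7, 1)),
#'                          seed = 42)
#' mutualInformation(getColumn(aln, 2), getColumn(aln, 7))
#' @export
generateAlignment <- function(nSeqs, nCols,
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                              couplings = list(), seed = 1L) {
  nSeqs <- as.integer(nSeqs); nCols <- as.integer(nCols)
  if (is.na(nSeqs) || nSeqs < 2L)
    stop("input error: 'nSeqs' must be >= 2")
  if (is.na(nCols) || nCols < 1L)
    stop("input error: 'nCols' must be >= 1")
  .checkBackground(background)
  pos <- unlist(lapply(couplings, function(cs) {
    if (!inherits(cs, "CouplingSpec"))
      stop("input error: 'couplings' must be a list of couplingSpec objects")
    c(cs$i, cs$j)
  }))
  if (any(pos > nCols))
    stop("input error: coupled position out of range 1..", nCols)
  if (anyDuplicated(pos))
    stop("input error: coupled pairs overlap at position ",
         pos[duplicated(pos)][1L])
  symbols <- names(background)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  seqs <- matrix(sample(symbols, nSeqs * nCols, replace = TRUE,
                        prob = background),
                 nrow = nSeqs, ncol = nCols)
  map <- .couplingMap(symbols)
  for (cs in couplings) {
    linked <- stats::runif(nSeqs) < cs$coupling
    seqs[linked, cs$j] <- map[seqs[linked, cs$i]]
  }
  MsaAlignment(seqs, ids = sprintf("seq%04d", seq_len(nSeqs)))
}

.checkBackground <- function(background) {
  if (is.null(names(background)) || any(!nzchar(names(background))))
    stop("input error: 'background' must be a named probability vector")
  if (!all(names(background) %in% AA_ALPHABET_EXT))
    stop("input error: background symbols must be in AA_ALPHABET_EXT")
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9)
    stop("input error: background probabilities must be >= 0 and sum to 1")
  invisible(background)
}

#' Population MI of a planted coupled pair
#'
#' Exact mutual information of the generative model behind
#' [generateAlignment()], obtained by summation over the finite joint
#' distribution implied by `coupling` and the background:
#' `p(x, y) = c * p(x) * [y == map(x)] + (1 - c) * p(x) * p(y)`.
#' Serves as the closed-form oracle for estimator-consistency tests.
#'
#' @param spec a [couplingSpec()] object.
#' @param background named symbol probability vector (as in
#'   [generateAlignment()]).
#' @param base logarithm base (2 = bits).
#' @return population MI.
#' @examples
#' expectedMI(couplingSpec(1, 2, 1))    # 2 bits for uniform 4 symbols
#' expectedMI(couplingSpec(1, 2, 0))    # 0
#' @export
expectedMI <- function(spec, background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       base = 2) {
  stopifnot(inherits(spec, "CouplingSpec"))
  .checkBackground(background)
  p <- as.numeric(background)
  k <- length(p)
  map <- .couplingMap(names(background))
  mapIdx <- match(map[names(background)], names(background))
  joint <- outer(p, p) * (1 - spec$coupling)
  joint[cbind(seq_len(k), mapIdx)] <-
    joint[cbind(seq_len(k), mapIdx)] + spec$coupling * p
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  terms[joint == 0] <- 0
  sum(terms) / log(base)
}
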