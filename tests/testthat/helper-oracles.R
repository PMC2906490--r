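# Independent reference implementations used as oracles. These deliberately
# take different code paths from the package (contingency tables instead of
# tabulate-coded counts; an explicit step-by-step greedy loop) so agreement
# is evidence of correctness, not of shared bugs.

# Mutual information in its direct Kullback-Leibler form:
# I = sum_{x,y} p(x,y) log[ p(x,y) / (p(x) p(y)) ]
oracleMI <- function(ci, cj, base = 2) {
  n <- length(ci)
  px <- table(ci) / n
  py <- table(cj) / n
  pxy <- table(ci, cj) / n
  s <- 0
  for (x in rownames(pxy)) {
    for (y in colnames(pxy)) {
      p <- pxy[x, y]
      if (p > 0) s <- s + p * log(p / (px[[x]] * py[[y]]), base = base)
    }
  }
  as.numeric(s)
}

# Shannon entropy from a symbol vector via table()
oracleEntropy <- function(col, base = 2) {
  p <- table(col) / length(col)
  -sum(p * log(p, base = base))
}

# Step-by-step greedy seed-row / L1 chaining, written as a literal trace:
# seed = first row of maximal sum; then repeatedly append the unplaced row
# with minimal L1 distance to the last placed row (first index on ties).
oracleSortRows <- function(m) {
  m[is.na(m)] <- 0
  sums <- apply(m, 1, sum)
  seed <- which(sums == max(sums))[1]
  placed <- seed
  remaining <- setdiff(seq_len(nrow(m)), seed)
  while (length(remaining) > 0) {
    last <- placed[length(placed)]
    d <- vapply(remaining,
                function(r) sum(abs(m[last, ] - m[r, ])), numeric(1))
    nxt <- remaining[which(d == min(d))[1]]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

# random alignment of canonical symbols drawn from the full extended alphabet
randomAlignment <- function(nSeqs, nCols, seed) {
  set.seed(seed)
  MsaAlignment(matrix(sample(AA_ALPHABET_EXT, nSeqs * nCols, replace = TRUE),
                      nrow = nSeqs))
}

# count lines of a triple file with i <= j (unique pairs, self-pairs included)
countUniquePairLines <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  f <- do.call(rbind, strsplit(trimws(ln), "[[:space:]]+"))
  sum(as.integer(f[, 1]) <= as.integer(f[, 2]))
}
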