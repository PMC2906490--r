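test_that("symbol encoding is a bijection with gap and non-standard handling", {
  expect_length(AA_ALPHABET_EXT, 22L)
  expect_identical(decodeSymbols(encodeSymbols(AA_ALPHABET_EXT)),
                   AA_ALPHABET_EXT)
  expect_identical(encodeSymbols(AA_ALPHABET_EXT), 1:22)
  # case-insensitive; '.' is a gap; anything unknown maps to the placeholder
  expect_identical(decodeSymbols(encodeSymbols(c("a", "w", "."))),
                   c("A", "W", "-"))
  expect_identical(decodeSymbols(encodeSymbols(c("B", "Z", "U", "*", "?"))),
                   rep("X", 5L))
  expect_false(AA_ALPHABET_EXT[21] == AA_ALPHABET_EXT[22])
  expect_error(decodeSymbols(23L), "1:22")
})

test_that("FASTA alignments are read with extended-alphabet encoding", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "AC-"), fa)
  aln <- readFastaAlignment(fa)
  expect_s4_class(aln, "MsaAlignment")
  expect_identical(nSequences(aln), 2L)
  expect_identical(nColumns(aln), 3L)
  expect_identical(seqIds(aln), c("a", "b"))
  expect_identical(alignmentMatrix(aln)[2, 3], "-")

  # non-standard residues become the placeholder; multi-line records are fine
  writeLines(c(">a", "ABZ", "U.", ">b", "ACDEF"), fa)
  aln2 <- readFastaAlignment(fa)
  expect_identical(alignmentMatrix(aln2)[1, ], c("A", "X", "X", "X", "-"))
})

test_that("malformed or degenerate FASTA input is rejected", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">bad", "ACDE"), fa)
  expect_error(readFastaAlignment(fa), "alignment error.*bad")
  writeLines(c(">only", "ACD"), fa)
  expect_error(readFastaAlignment(fa), "input error.*2 FASTA records")
  writeLines(character(0), fa)
  expect_error(readFastaAlignment(fa), "error")
  writeLines(c("ACD", "ACC"), fa)  # no header line
  expect_error(readFastaAlignment(fa), "error")
  expect_error(readFastaAlignment(file.path(tempdir(), "absent.fa")),
               "not found")
  writeLines(c(">dup", "AC", ">dup", "CC"), fa)
  expect_warning(readFastaAlignment(fa), "duplicate")
})

test_that("getColumn returns columns in record order with index checks", {
  aln <- MsaAlignment(c("AC", "GC"), ids = c("a", "b"))
  expect_identical(getColumn(aln, 1), c("A", "G"))
  expect_identical(getColumn(aln, 2), c("C", "C"))
  expect_error(getColumn(aln, 3), "index error")
  expect_error(getColumn(aln, 0), "index error")
  # consistency with the alignment matrix at every position
  aln2 <- randomAlignment(5, 4, seed = 11)
  for (j in 1:4)
    expect_identical(getColumn(aln2, j), alignmentMatrix(aln2)[, j])
})

test_that("FASTA round trip preserves the alignment", {
  aln <- randomAlignment(6, 9, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeFastaAlignment(aln, fa)
  back <- readFastaAlignment(fa)
  expect_identical(alignmentMatrix(back), alignmentMatrix(aln))
  expect_identical(seqIds(back), seqIds(aln))
})

test_that("triple-format writer emits row-major 1-based lines, skipping NA", {
  f <- withr::local_tempfile(fileext = ".mat")
  writeMatrixTriples(rbind(c(1, 2), c(2, 4)), f)
  ln <- readLines(f)
  expect_identical(ln[1], "# row column value")
  expect_identical(ln[2], "1 1 1")
  expect_identical(ln[3], "1 2 2")
  expect_length(ln, 5L)

  m <- rbind(c(1, NA), c(2, 4))
  writeMatrixTriples(m, f)
  expect_false(any(grepl("^1 2 ", readLines(f))))
})

test_that("triple-format round trip is lossless for doubles", {
  set.seed(42)
  m <- matrix(runif(25) * 1e3 - 500, 5)
  f <- withr::local_tempfile(fileext = ".mat")
  writeMatrixTriples(m, f)
  expect_identical(readMatrixTriples(f), m)
})

test_that("triple-format reader handles dialects, gaps and bad input", {
  f <- withr::local_tempfile(fileext = ".mat")
  writeLines(c("1 1 0.5", "1 2 0.1", "2 2 0.7"), f)
  m <- readMatrixTriples(f)
  expect_identical(dim(m), c(2L, 2L))
  expect_true(is.na(m[2, 1]))  # no symmetric completion
  expect_identical(m[1, ], c(0.5, 0.1))

  # comma-separated variant reads identically; blank and # lines are ignored
  writeLines(c("# comment", "", "1,1,0.5", "1, 2, 0.1", "2,2,0.7"), f)
  expect_identical(readMatrixTriples(f), m)

  writeLines(c("1 x 0.5"), f)
  expect_error(readMatrixTriples(f), "parse error at line 1")
  writeLines(c("1 1 0.5", "1 1 0.7"), f)
  expect_error(readMatrixTriples(f), "duplicate cell")
  writeLines(c("0 1 0.5"), f)
  expect_error(readMatrixTriples(f), "parse error")
  writeLines("# header only", f)
  expect_identical(dim(readMatrixTriples(f)), c(0L, 0L))
})

test_that("MsaAlignment validity enforces alignment invariants", {
  expect_error(MsaAlignment(c("ACD", "AC")), "same length")
  expect_error(MsaAlignment("ACD"), "at least 2 sequences")
  aln <- MsaAlignment(c("acd", "ac-"))
  expect_true(all(alignmentMatrix(aln) %in% AA_ALPHABET_EXT))
})
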