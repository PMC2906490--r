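test_that("column shuffling conserves the symbol multiset and entropy", {
  set.seed(5)
  for (rep in 1:20) {
    col <- sample(AA_ALPHABET_EXT, 30, replace = TRUE)
    shuf <- shuffleColumn(col)
    expect_identical(sort(shuf), sort(col))
    # entropy conservation must be bit-identical, not just approximate
    expect_identical(columnEntropy(shuf), columnEntropy(col))
  }
  set.seed(99); a <- shuffleColumn(letters)
  set.seed(99); b <- shuffleColumn(letters)
  expect_identical(a, b)
  expect_error(shuffleColumn(character(0)), "empty column")
})

test_that("sampleNull returns symmetric per-pair statistics deterministically", {
  aln <- generateAlignment(25, 6, seed = 8)
  null <- sampleNull(aln, nReplicates = 30, seed = 4)
  expect_s4_class(null, "ShuffleNull")
  expect_identical(nullMean(null), t(nullMean(null)))
  expect_identical(nullSd(null), t(nullSd(null)))
  expect_true(all(nullSd(null) >= 0))
  expect_identical(nReplicates(null), 30L)
  # bit-identical reproducibility under the same (alignment, n, seed) triple
  null2 <- sampleNull(aln, nReplicates = 30, seed = 4)
  expect_identical(nullMean(null2), nullMean(null))
  expect_identical(nullSd(null2), nullSd(null))
  expect_error(sampleNull(aln, nReplicates = 1), "input error")
})

test_that("shuffling a constant-column pair is a no-op in the null", {
  aln <- MsaAlignment(c("AA", "AA", "AA", "AA"))
  null <- sampleNull(aln, nReplicates = 10, seed = 1)
  expect_identical(nullMean(null)[1, 2], 0)
  expect_identical(nullSd(null)[1, 2], 0)
})

test_that("null mean matches an independent re-implementation (Monte Carlo)", {
  # two independent uniform 4-symbol columns, n = 200 sequences
  aln <- generateAlignment(200, 2, seed = 17)
  R <- 500
  null <- sampleNull(aln, nReplicates = R, seed = 101)
  # independent route: explicit sample() shuffles + KL-form oracle MI,
  # different seed
  ci <- getColumn(aln, 1); cj <- getColumn(aln, 2)
  set.seed(202)
  mis <- replicate(R, oracleMI(sample(ci), sample(cj)))
  se <- sqrt(stats::var(mis) / R + nullSd(null)[1, 2]^2 / R)
  expect_lt(abs(nullMean(null)[1, 2] - mean(mis)), 3 * se)
})

test_that("Z-scores implement per-pair standardization with sd-zero masking", {
  aln <- generateAlignment(30, 4, seed = 2)
  mi <- miMatrix(aln)
  null <- sampleNull(aln, nReplicates = 50, seed = 3)
  # centering: observed equal to the null mean gives Z = 0
  z0 <- zScores(nullMean(null), null)
  expect_true(all(z0[nullSd(null) > 0] == 0))
  # hand value: MI 0.5, mean 0.2, sd 0.1 -> Z = 3
  handNull <- new("ShuffleNull", mean = matrix(0.2, 1, 1),
                  sd = matrix(0.1, 1, 1), nReplicates = 10L, seed = 1L,
                  base = 2)
  expect_equal(zScores(matrix(0.5, 1, 1), handNull)[1, 1], 3.0)
  # degenerate null: constant columns give NA, never +-Inf
  alnC <- MsaAlignment(c("AAC", "AAC", "AAA", "AAC"))
  miC <- miMatrix(alnC)
  nullC <- sampleNull(alnC, nReplicates = 10, seed = 5)
  zC <- zScores(miC, nullC)
  expect_true(all(is.na(zC[nullSd(nullC) == 0])))
  expect_false(any(is.infinite(zC), na.rm = TRUE))
  expect_error(zScores(mi[1:3, 1:3], null), "input error")
})

test_that("Z-scores are invariant under a change of entropy log base", {
  aln <- generateAlignment(40, 6, couplings = list(couplingSpec(1, 4, 0.8)),
                           seed = 12)
  z2 <- zScores(miMatrix(aln, base = 2),
                sampleNull(aln, 60, seed = 7, base = 2))
  ze <- zScores(miMatrix(aln, base = exp(1)),
                sampleNull(aln, 60, seed = 7, base = exp(1)))
  expect_equal(ze, z2, tolerance = 1e-9)
})

test_that("the null destroys planted coupling", {
  aln <- generateAlignment(60, 4, couplings = list(couplingSpec(2, 3, 1)),
                           seed = 31)
  mi <- miMatrix(aln)
  null <- sampleNull(aln, nReplicates = 100, seed = 32)
  expect_lt(nullMean(null)[2, 3], mi[2, 3])
})
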