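# coevoMI

Detecting co-evolving residue pairs in protein multiple sequence alignments
with mutual information, a column-shuffle null model, and matrix
visualization post-processing.

## The problem

When two sites in a protein evolve in concert — through folding constraints,
electrostatics, shared binding interfaces — their alignment columns become
statistically dependent. The standard detector of this dependence is the
mutual information between columns *i* and *j*,

    MI_ij = H_i + H_j − H_ij

where `H_i = −Σ_x p_i(x) log₂ p_i(x)` is the Shannon entropy of column *i*
and `H_ij` the joint entropy of the column pair, with all probabilities set
to observed symbol frequencies over a 22-letter alphabet (20 standard amino
acids, the gap `-`, and `X` for non-standard residues). Self-pairs give
`MI_ii = H_i`, so an `L`-column alignment yields `L(L+1)/2` unique values
(5050 for `L = 100`) — too many to scan by eye, and biased upward when only
~10² sequences feed a 22-symbol estimator.

`coevoMI` addresses both problems the way the field does:

1. **Normalization.** A column-shuffle null model: each column is
   independently permuted across sequences, which preserves every
   single-column entropy while destroying inter-column correlation. Over
   many shuffle replicates the per-pair mean `⟨MI_ij⟩` and standard
   deviation `σ(MI_ij)` define a Z-score

       Z_ij = (MI_ij − ⟨MI_ij⟩) / σ(MI_ij)

   that standardises each observed value against its own finite-sample null.
2. **Visual analysis.** Greedy seed-row/L1 seriation brings similar rows and
   columns together, inclusive range filters on MI and Z isolate the
   interesting cells, a weight matrix can multiply the data or drive color
   saturation, and the result is exported as a lossless, byte-deterministic
   PNG heatmap plus plain-text data subsets.

Matrices travel between the compute and render stages as plain ASCII files,
one `row column value` triple per line, so either stage can run on its own
(e.g. the compute stage on a cluster).

## Worked example

Plant one coupled column pair (positions 5 and 20, coupling 0.9) in an
otherwise independent 200-sequence, 30-column alignment, and ask the
pipeline to find it:

```r
library(coevoMI)

aln <- generateAlignment(200, 30,
                         couplings = list(couplingSpec(5, 20, 0.9)),
                         seed = 42)
mi   <- miMatrix(aln)                              # bits
null <- sampleNull(aln, nReplicates = 100, seed = 43)
z    <- zScores(mi, null)

mi[5, 20]   # 1.5905  — observed MI of the planted pair, in bits
mi[5, 5]    # 1.9849  — entropy of column 5 (the diagonal)
z[5, 20]    # 96.46   — far above anything the null produces
```

The planted pair towers over the background: the next-highest off-diagonal
Z-score in this run is 4.63. An inclusive filter `applyFilter(mi, z,
zRange = c(3, Inf))` keeps 7 of the 435 off-diagonal pairs — the planted
(5, 20) plus 6 borderline false positives at `Z` ≈ 3–4.6, the expected tail
at this threshold. Rendering:

```r
sr  <- sortMatrix(mi)                       # seed-row / L1 seriation
img <- renderMatrix(normalizeValues(sortedMatrix(sr)), "sequential")
exportPNG(img, "mi.png")                    # one pixel per pair
```

The same pipeline from a shell (the script is installed with the package):

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "coevmi.R", package = "coevoMI"))')
Rscript $CLI fixtures --n-seqs 200 --n-cols 30 --couple 5:20:0.9 --seed 42 -o aln.fasta
Rscript $CLI compute aln.fasta -o out --shuffles 100 --seed 43
Rscript $CLI render out/mi.mat -w out/z.mat -o mi.png --sort \
        --z-range 3:inf --export-subset hits.txt
```

`out/mi.mat` and `out/z.mat` are the triple-format matrices, `hits.txt` the
filter-surviving cells with original position labels, and `mi.png.labels.txt`
maps displayed rows/columns back to alignment positions after sorting.

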