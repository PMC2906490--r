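---
title: "Mutual-information co-evolution analysis: models, null distributions, and design choices"
author: "coevoMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information co-evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoMI)
```

# The measure

Two alignment columns that evolve in concert are statistically dependent,
and the canonical quantification of that dependence is the mutual
information. For columns $i$ and $j$ of a multiple sequence alignment, with
symbol probabilities set to the observed relative frequencies (the plug-in
estimator),

$$\mathrm{MI}_{ij} \;=\; H_i + H_j - H_{ij}, \qquad
H = -\sum_x p(x)\,\log_2 p(x),$$

computed over a 22-symbol alphabet: the 20 standard amino acids, the gap
character, and one placeholder (`X`) for every non-standard residue code.
Gaps and placeholders are ordinary symbols here — the alphabet is extended
rather than the data filtered, so strongly gapped columns contribute real
(and interpretable) entropy instead of being silently dropped. The matrix is
symmetric; the diagonal carries the column entropies ($\mathrm{MI}_{ii} =
H_i$), so an $L$-column alignment has $L(L+1)/2$ unique values.

Identities used by the test suite as oracles: the entropy-difference form
above must agree with the direct summation
$\sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}$ to $10^{-12}$;
$\mathrm{MI}(X,X) = H(X)$; and $0 \le \mathrm{MI}_{ij} \le \min(H_i, H_j)$.

**Units.** Entropies default to bits (`base = 2`); `base = exp(1)` gives
nats. The choice cancels exactly in the Z-scores below, which the suite
verifies to $10^{-9}$.

# The null model

With $n \sim 10^2$ sequences against a 22-symbol (484-pair) alphabet, the
plug-in estimator is biased upward: even independent columns show positive
MI. Rather than an analytic bias correction (Miller–Madow and relatives),
the package follows the shuffle-null approach: each column is independently
permuted across sequences, preserving every single-column entropy exactly
(the symbol multiset is untouched) while destroying all inter-column
correlation. Repeating this `nReplicates` times gives, per pair, a sample of
MI values under neutral (uncorrelated) evolution with the *same marginal
compositions* as the data, from which

$$Z_{ij} = \frac{\mathrm{MI}_{ij} - \langle \mathrm{MI}_{ij}\rangle}
{\sigma(\mathrm{MI}_{ij})}.$$

Choices made where the procedure leaves room:

* **All columns are re-permuted per replicate** and the whole MI matrix
  recomputed, rather than shuffling one column of each pair at a time; the
  cost is identical asymptotically and one replicate serves every pair.
* **Sample standard deviation** uses the $n-1$ denominator.
* **$\sigma = 0$ pairs** (e.g. invariant columns, which a shuffle cannot
  change) have no defined Z and are masked as `NA` — never $\pm\infty$.
  They are omitted from triple-file exports and get zero weight in
  rendering.
* **Default `nReplicates = 100`**, always overridable. At 100 replicates the
  per-pair standard error of the null mean is $\sigma/10$, ample for a
  screening Z-score; users chasing marginal $Z \approx 3$ calls should
  raise it.
* **Accumulation** uses Welford's online mean/variance update, which is
  cancellation-free: shuffle-invariant pairs get an sd of exactly 0 (and are
  masked) instead of a $10^{-8}$ round-off artifact that would explode into
  a huge spurious Z.
* **Determinism.** One R RNG stream is seeded once per `sampleNull` call and
  columns are shuffled in a fixed order, so identical (alignment,
  `nReplicates`, `seed`) inputs give bit-identical statistics. The caller's
  RNG state is saved and restored.
* **Clamping.** MI values are clamped at zero (floating-point cancellation
  can produce $-10^{-16}$); observed and null replicate matrices pass
  through the same pipeline, so Eq.-consistency between numerator terms is
  preserved and the clamp is invisible above $10^{-15}$.

# Matrix seriation

The display-ordering algorithm is deliberately simple and fully
deterministic: the *seed row* is the row with the maximal sum of contained
values; it is placed first, and the chain greedily appends the unplaced row
with the smallest $l_1$ distance to the previously placed row. The same pass
is then applied to the columns **of the row-reordered matrix** (the passes
are sequential and independent, so a symmetric matrix may receive different
row and column orders — no symmetry coupling is imposed). Quadratic time.

Two under-determined points are fixed as follows: all ties (seed selection
and nearest-row selection) break toward the lowest original index, which
makes the algorithm testable against a brute-force trace; and masked cells
contribute 0 to sums and distances, keeping the algorithm total on filtered
matrices. Both permutations are returned so exports and axis labels can
always refer to original alignment positions. This is a starting point for
visual analysis, not optimal seriation; hierarchical-leaf or spectral
ordering is out of scope.

# Filtering, weighting, rendering

* Range filters on MI and Z are **inclusive on both ends**, so exact
  threshold hits survive; a cell with undefined Z fails any Z-bounded
  filter. Filters produce masks and never mutate values.
* A weight matrix (typically Z) can be **multiplied** into the data
  elementwise (`NA` propagates), or drive **color saturation** through a
  linear ramp clamped to $[0,1]$ between user bounds — the minimal
  documented transfer function.
* Normalization for display is global min–max by default (a constant matrix
  maps to 0.5); a fixed range is available for comparable images across
  runs.
* Rendering paints one `cellPx`-square block per cell (1 pixel per pair at
  `cellPx = 1`), masked cells in the scale's background color, and
  saturation blending linearly in RGB toward the background. Channels are
  quantized to 8 bits *before* writing, making PNG export lossless
  (decode returns the exact pixel array) and byte-deterministic.
* Histograms count unmasked cells in equal-width bins; for symmetric
  matrices an option counts each unordered pair once, matching the
  $L(L+1)/2$ accounting.

# Interchange format

Matrices move between stages as plain ASCII triples, `row column value`, one
stored cell per line, 1-based indices in original alignment coordinates
(residue numbering survives sorting and sub-setting). The writer emits
space-separated lines at 17 significant digits (lossless for doubles) plus a
`#` header; the reader also accepts comma separators, ignores blank and `#`
lines, rejects duplicate cells, and performs **no** symmetric completion —
absent cells stay missing. The full symmetric matrix (diagonal included) is
exported by the compute command; unique-pair accounting simply counts lines
with $i \le j$.

# The synthetic generator

`generateAlignment()` emulates exactly what the statistics need and no more:
uncoupled columns are i.i.d. draws from a background symbol distribution,
and a planted pair follows a *probabilistic bijective relabeling* — with
probability `coupling` the symbol at position $j$ is a fixed bijection
(cyclic shift) of the symbol at $i$, otherwise an independent background
draw. This mechanism was chosen because its population MI has a closed form
(`expectedMI()` enumerates the joint table exactly), giving the
estimator-consistency tests an independent oracle: `coupling = 1` makes MI
equal the column entropy; `coupling = 0` gives exact independence.

The default background is uniform over four symbols (A, C, G, T — all valid
amino-acid codes): high-entropy columns at low alphabet cost, so planted
signals are strong and the finite-sample bias regime is still exercised.
Full 22-symbol backgrounds are supported.

What the generator does **not** emulate: phylogenetic correlation between
sequences (rows are exchangeable by construction), realistic substitution
processes, gap structure, or multi-site epistatic networks. Passing tests
therefore demonstrate the estimator, the null model and the pipeline
mechanics — not that biological co-evolution in a real family will separate
this cleanly, where shared ancestry inflates MI in ways a column shuffle
cannot remove.

# Study conditions used by the tests

The suite and the acceptance script run at sizes chosen to be statistically
meaningful yet quick on one CPU: oracle equivalence on 100 random
alignments ($n \le 8$, $L \le 6$); seriation against a brute-force trace on
$L \le 5$; null-model self-consistency at $n = 200$, 500 replicates; signal
recovery at $L = 30$, $n = 200$, coupling 0.9, 100 replicates (the planted
pair must attain the top off-diagonal Z and survive a $Z \ge 3$ filter,
while an unplanted alignment keeps its $Z > 3$ rate below 5%); estimator
consistency at $n \in \{10^2, 10^3, 10^4\}$ within $3/\sqrt{n}$ bits; and
the 5050-pair count at $L = 100$.

# Known limitations

* No correction for phylogenetic redundancy (sequence weighting, average
  product correction, DCA-style couplings) — the Z-score corrects
  finite-sample bias, not shared ancestry.
* The shuffle null stops at Z-scores; no p-values or multiple-testing
  control are attached.
* Greedy seriation is order-dependent and not optimal; it is a visual aid.
* The null-model cost scales as `nReplicates` full MI matrices
  ($O(R \cdot L^2 \cdot n)$); for $L$ in the many hundreds, run the compute
  command in batch.
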