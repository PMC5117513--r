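---
title: "Detecting positional clusters of TF motifs in TSS-anchored promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positional clusters of TF motifs in TSS-anchored promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promclust)
```

## The question and the model

Transcription factors (TFs) that act together in a regulatory module (RM)
bind sites with tight positional preferences relative to each other and,
often, relative to the transcription start site (TSS). Given a gapless
block of promoter sequences anchored on the TSS — every sequence the same
length, the TSS base in the same alignment column — a TF with a positional
preference leaves a footprint: motif scores pile up in a few alignment
columns instead of spreading evenly.

`promclust` quantifies that footprint in four stages.

**1. Column scores.** Every (sequence, position, strand) triple is scored
with a log-odds statistic: the motif model probability of the site letters
(from a JASPAR-style count matrix with a symmetric Dirichlet pseudo-count
of 0.5 per nucleotide) against a background probability from a
position-varying Markov model. A *motif* is any positive-scoring site;
each motif is assigned to the alignment column of its 3' base. The column
score `x_i >= 0` aggregates motif scores per column (by default the sum of
the positive scores; a variant clamps the total raw sum at zero).

**2. Background.** Promoter composition changes with distance from the
TSS, so background probabilities are re-estimated every 23 columns from a
3rd-order Markov model fitted to a 50-column window
(24 columns 5' + 23 + 3 columns 3'): the 5' pad covers the widest scanned
matrix (21 columns) plus a 3-letter left context, the 3' pad a 3-letter
right context, so any site whose 3' base lies in a block is scored from
data inside that block's own window. Site probabilities condition on both
flanking letter-triples ("context-2"): by Bayes' rule
`P(site | left, right) = P(site | left) * P(right | site tail) / P(right | left)`,
with the denominator computed by propagating the chain's 64x64 state
transfer matrix across the site's width. Summed over all `4^w` sites the
conditional is exactly 1 (a property the test suite checks exhaustively
for `w <= 5`). At alignment edges the conditioning falls back to the
available shorter context so every column remains scoreable.

**3. Clusters.** With a per-column gap penalty `g` subtracted, maximal
scoring runs of columns are found with the Ruzzo-Tompa algorithm; each
maximal segment is a candidate cluster, its score the sum of `x_i - g`
over its columns. The penalty is normalized per TF, `g = rho * mean(x)`,
with a single shared `rho = 1.4`; `rho > 1` keeps the statistic in the
logarithmic (extreme-value) regime, and larger `rho` tightens the
clusters. `tune_rho()` reports median cluster spread over a grid and
recommends the smallest value achieving spreads of at most 10 bp,
matching the biological expectation that a positional preference inside
an RM is tight (about ±5 bp).

**4. Significance and co-occurrence.** Cluster scores get
Karlin–Altschul p-values `p = 1 - exp(-K n e^{-lambda * S})` with `K = 1`,
plus an optional permutation p-value. Clusters significant after a
Bonferroni correction over (#matrices × #strands) tests each define a
*gene group* — the distinct genes contributing motifs to the cluster.
Every unordered pair of gene groups is tested for intersection enrichment
with exact Fisher (hypergeometric) tails against the dataset's own gene
universe, never a global gene catalogue: promoter databases are biased
samples, and using the dataset as universe absorbs that bias. Right tails
discover enrichment; left tails serve only as a negative control.

## Estimating lambda under signal

`lambda` solves the empirical moment equation
`mean(exp(lambda * (x_j - g))) = 1`. Solved on the *observed* scores this
is self-defeating whenever real signal is present: the signal column
dominates the mean, capping `lambda * S` near `log n`, so the statistic
could never reach the tiny p-values that motivate it. `find_clusters()`
therefore fits `lambda` on a permutation-null rebuild of the column
scores: the observed motif scores are redistributed i.i.d. uniformly over
the columns (three pooled replicates, fixed internal seed, deterministic
and invariant to input order). The rebuild preserves the number and
magnitude of the motif scores while destroying positional structure —
exactly the null hypothesis the p-value describes. On signal-free data the
rebuild matches the observed score distribution (slightly heavier in the
tail, which keeps the p-values conservative); under signal it gives an
uncontaminated null estimate, and its ranking agrees with the calibrated
permutation p-value across the whole signal range (a property test
enforces Spearman ≥ 0.9 on a graded-signal batch).

`K = 1` is a deliberate Poisson-clumping upper bound: the cluster p-value
is conservative by design, and the permutation p-value is the calibrated
alternative against which it is tested.

## What the synthetic generators emulate

The generators stand in for a TSS-anchored promoter database (which is
derived from large external resources and cannot be shipped):

* fixed-length sequences over {A,C,G,T} with the TSS at a fixed column
  (defaults 3001 bp, TSS at 0-based column 2000, coordinates −2000..−1 and
  +1..+1001 with no position 0);
* many-to-one sequence→gene redundancy (each gene emits 1–5 independent
  background duplicates by default, echoing the roughly 5× redundancy of
  real promoter databases);
* an optional GC gradient rising linearly toward the TSS, emulating
  GC-rich proximal promoters;
* planted RMs: per carrier gene, each member site is sampled column-wise
  from the member's probability matrix (so weak draws can genuinely be
  missed — scoring false negatives are exercised), written at a fixed
  offset from the TSS into all of the gene's duplicates, with optional
  per-gene positional jitter;
* two negative controls: i.i.d. random blocks, and "random with offsets"
  blocks in which each gene's sequences are offset copies of one random
  source string, reproducing the overlap structure of a redundant
  promoter database without any signal (offsets uniform on ±500 bp by
  default; the real database's offset law is unknown, so this is a
  reasoned stand-in).

What passing tests on these fixtures do *not* show: real promoters have
repeat content, CpG islands, composition biases correlated with gene
function, and TSS annotation error; none of these are emulated, so planted
recovery rates here are upper bounds on what identical settings would
achieve on biological data.

## Numerical and design choices

* Columns are 0-based internally; the TSS base is the 0-based column
  `tss_col` and carries coordinate +1. *Spread* is reported as the number
  of columns in a segment, which equals `To − From + 1` except for
  segments straddling the TSS (the coordinate line skips 0).
* Replicate filtering keeps the first occurrence in input order;
  filtering is idempotent.
* Ruzzo-Tompa tie policy: zero-scoring extensions are excluded, so each
  reported segment is the shortest member of its tied family
  (deterministic; verified against exhaustive recursive extraction).
* The moment equation is solved by bracketed root finding on
  `log mean exp` (overflow-safe) to ~1e-12, polished with Newton steps;
  the root satisfies the equation within 1e-9.
* Minus-strand sites are scored by applying the reverse-complemented
  matrix to plus-strand letters; the background is always evaluated on
  plus-strand letters (one background model serves both strands), and the
  block whose tables apply is the one containing the motif's assigned
  (3'-base) column. Tables report minus-strand clusters in plus-strand
  coordinates.
* The permutation null redistributes individual hit scores i.i.d.
  uniformly over all columns; column-label permutation is available as an
  option. Under the `clamped_total` column policy the rebuild uses the
  motif (positive) scores, which are what the null preserves.
* Fisher tails are exact (no mid-p), via the hypergeometric distribution.
* The intersection threshold can be `alpha / C(k,2)` or
  `alpha / (2 C(k,2))` (both tails corrected); both conventions appear in
  the reporting around this statistic, so the pipeline records which one a
  run used.

## Problem sizes used by the tests and acceptance script

Chosen to exercise every stage at desk scale:

* null calibration: 300 sequences × 600 columns, 200 seeds, one width-8
  synthetic matrix (dominance 0.9), permutation p with 99 replicates;
* planted-module recovery and negative controls: 400 genes with 1–3
  duplicates (~800 sequences) × 1001 columns, TSS at column 600, a
  two-member module (widths 5 and 4, dominance 0.95, strands +) at
  offsets +7 and +12 in 30% of genes, 10 seeds;
* `rho` robustness: the same planted fixture, segments compared across
  `rho` ∈ {1.3, 1.4, 1.5};
* Fisher oracle: every table with universe ≤ 30, exhaustively;
  Ruzzo-Tompa oracle: 500 random instances, n ≤ 50.

Full biological scale (tens of thousands of sequences × 3001 columns × 53
matrices) is a straightforward scale-up of the same code paths.

## Known limitations

* Calibration of the *permutation* p-value is slightly conservative when
  the background is fitted on the same block being scanned (the package's
  and the method's normal operation): the adaptive fit absorbs chance
  composition fluctuations, so observed hit placement is underdispersed
  relative to the i.i.d. redistribution null. With a background fitted on
  independent data the permutation p is uniform; with the self-fitted
  background its distribution on null blocks shifts toward 1. All
  deviations are in the conservative direction.
* `K = 1` overstates the expected number of high-scoring clusters; the
  reported analytic p-values are upper bounds.
* The context-2 background formula is an exact Bayes construction under
  the fitted chain; other reconstructions of two-sided conditioning are
  possible.
* Lattice effects in the discrete score distribution are ignored (no
  lattice correction in the Karlin-Altschul tail).
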