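---
title: "Gene-signature discovery with sigevolve: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-signature discovery with sigevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigevolve)
```

## The problem

Given a two-class gene-expression cohort — the motivating design is
glioblastoma (GBM, the positive class) against lower-grade gliomas on a
single-channel microarray platform — we want a *compact signature*: a small
set of genes whose expression jointly separates the classes, each tagged as
over- or underexpressed in the positive class. Univariate ranking alone
over-reports correlated genes and ignores joint effects; a pure wrapper
search over tens of thousands of genes is computationally hopeless and
overfits. The pipeline therefore has two stages:

1. **Screening** reduces the universe to a candidate panel (default 100
   genes: the 50 most overexpressed and 50 most underexpressed by
   signal-to-noise, optionally restricted to genes carried by positively
   enriched pathway-style gene sets).
2. **Wrapper selection** runs a genetic algorithm (GA) over binary gene
   subsets of the panel, scoring each subset by the cross-validated,
   grid-searched performance of an RBF-kernel support vector machine (SVM)
   under four fitness measures, and aggregates the top solutions into
   per-gene *selective scores* from which the signature is thresholded.

## Stage by stage

### Normalization

Raw linear intensities are scaled per array so every sample's two-sided
trimmed mean equals a common target (`linear_scale()`, defaults: trim 2%,
target 500 — the conventional global-scaling target signal for this class
of arrays), then floored and log2-transformed (`log2_transform()`, floor 1
so zero intensities map to 0). Only a per-sample multiplicative factor is
applied, so within-sample rank order is untouched. Background correction,
quantile normalization and probe-level summarization are out of scope: data
already summarized per gene are expected, and cohorts normalized upstream
can skip straight to the log2 matrix.

### Signal-to-noise ranking and enrichment screening

For each gene, `signal_to_noise()` computes
\((\mu_{pos}-\mu_{neg})/(\sigma_{pos}+\sigma_{neg})\) on the log2 scale.
Each class standard deviation is floored at \(0.2\,|\mu|\) of its class
mean (and at 0.2 when that is still zero) — the standard guard that stops
near-constant genes from producing unbounded ratios. Ties in the ranking
break lexicographically by gene id so results are reproducible across
platforms and hash orders.

`enrichment_score()` walks the ranked list with a running sum that rises at
members of a gene set and falls elsewhere. Member increments are
\(|s|^w\) normalized to total 1 over the set; non-members decrement by
\(1/(N-|S|)\). The enrichment score is the *signed maximum* of the walk. The
weight exponent defaults to 1; `weight_exponent = 0` gives the classic
unweighted (Kolmogorov–Smirnov-like) walk in which a set occupying the top
\(k\) ranks scores exactly 1. Permutation significance (normalized scores,
FDR) is deliberately not implemented: here enrichment is a screening
device, not an inference procedure.

`screen_candidates()` then takes the top and bottom `n_per_tail` genes. Two
readings of "screen by enrichment" are defensible: rank genes and use sets
only as an eligibility filter, or rank sets and pool their genes. We expose
the choice as `restrict_to_sets`: when on (the default whenever sets are
supplied), only genes belonging to at least one *positively* enriched set
are eligible for the panel; when off, the panel is purely signal-to-noise.
Neither reading is silently preferred; the flag records which was used.

### SVM fitness

A chromosome is a 0/1 vector over the panel; its fitness
(`evaluate_fitness()`) is the best value over an exponential
\((C, \gamma)\) grid — \(2^{-15}\) to \(2^{15}\), unit steps by default,
`grid_step = 4` for the 8×8 desk grid — of the chosen measure computed from
a *single pooled confusion table* of out-of-fold predictions under
stratified 5-fold cross-validation. Pooling (rather than averaging
per-fold measures) is used because MCC and F1 on 10-sample folds are
unstable and frequently undefined; a pooled table keeps every fitness value
well-defined and totally ordered. Folds are drawn once per selection run
from the master seed and reused for every chromosome, making fitness a pure
function of the bit vector (and enabling an internal cache shared across
measures and repeats).

The four measures, from confusion counts (positive class = the phenotype of
interest):

- accuracy \((TP+TN)/N\);
- Matthews correlation coefficient, with the value 0 when a margin of the
  table is zero;
- F1, the harmonic mean of precision and sensitivity, 0 when \(TP = 0\);
- hybrid \(= \text{sensitivity} + \delta \cdot \text{specificity}\), with
  \(\delta = n_{pos}/n_{neg}\) counterweighting class imbalance.

The all-zero chromosome receives the measure's minimum (−1 for MCC, 0
otherwise) as a sentinel: comparable, never preferable to a valid subset.

The inner solver is a compiled SMO C-SVC working on a kernel matrix
precomputed once per chromosome and shared across the whole grid and all
folds, with solutions warm-started along the ascending-cost path. Its
stopping tolerance (1e-3) and working-set selection follow standard
practice, and fully converged results are verified against the libsvm
binding (e1071) in the test suite. One numerical knob matters:
`max_iter` (default 200 per solve) truncates the nearly flat-kernel corner
of the grid (tiny \(\gamma\) with large \(C\)), where exact convergence
takes ~10^5 iterations while changing the pooled predictions negligibly —
measured grid-max fitness differs by at most 0.04 from full convergence
across random chromosomes. Raise `max_iter` when libsvm-exact grid values
are required.

### The genetic algorithm

Per generation (`run_ga()`): evaluate all fitnesses → elitist selection →
mutation → crossover, in that order. Selection keeps one elite per
population half — the better of the half's best and the previous elite,
ties resolving to the lowest index and to the incumbent — and refills the
next generation with copies (odd positions from the first-half elite, even
from the second). Before the first generation the elites are *virtual*
(fitness 0, empty chromosome); virtual elites lose ties so they can never
propagate an empty chromosome into the population. Mutation flips each bit
of the first half with probability 0.1 and exactly one random bit in each
second-half chromosome — one half explores broadly, the other locally.
One-point crossover swaps suffixes within consecutive pairs with
probability 0.5. Defaults: 80 chromosomes, 200 generations, 10 repeats per
measure.

The generation-best records across `repeats × generations` (2,000 at
defaults) per measure are deduplicated by bit vector and ranked by fitness
(`run_selection_procedure()`); the top 10 feed the scoring stage. Fewer
than 10 unique solutions is flagged as a shortfall, and missing ranks
contribute 0 to the scores below (the divisors stay fixed) — conservative
and monotone, rather than renormalizing which would inflate sparse
archives.

### Selective scores and the signature

For gene \(j\), with \(f_j^q\) its bit in the \(q\)-th ranked solution of a
measure:

\[
r_j = \frac{1}{4}\sum_{p=1}^{4}\left(\frac{1}{10}\sum_{q=1}^{10} f_j^q
+ \frac{1}{5}\sum_{q=1}^{5} f_j^q + f_j^1\right)
\]

so \(r_j \in [0, 3]\), presence near the top of a ranking counts up to
three times, and 3 is attained exactly by a gene present in every counted
solution of every measure. `extract_signature()` keeps genes with
\(r_j \ge 2\) (threshold exposed), and `combine_signatures()` merges two
cohorts' signatures with union/intersection bookkeeping, flagging (not
dropping) direction conflicts. `heatmap_matrix()` exports the z-scaled,
class-grouped submatrix for plotting with any heatmap tool.

## The synthetic-data generator

`gen_two_class_expression()` emulates a two-class, single-channel
microarray experiment in log2 space: every value is
\(\text{baseline} + \text{class shift} + \mathcal{N}(0, \sigma)\), with
planted overexpressed genes shifted \(+\text{effect}\) and underexpressed
genes \(-\text{effect}\) in the positive class only. Defaults mirror the
motivating cohort: 228 positive vs 148 negative samples, baseline log2
intensity 8, noise sd 1 (a typical residual spread for such arrays), and a
planted effect of 2 log2 units (four-fold) — a strongly differential gene.
The universe defaults to 1,000 genes, large enough for the default
screening tails while keeping desk-scale runs cheap.
`gen_gene_sets()` adds a pathway-like collection in which a configurable
fraction of sets draws at least half its members from planted genes.

What the generator does *not* emulate — probe-level structure, batch
effects, correlated co-expression blocks, heavy-tailed noise, missing
values — bounds what passing tests mean: they validate the machinery
(ranking, enrichment arithmetic, fitness, GA bookkeeping, scoring) under a
clean Gaussian independence model, not robustness to real microarray
artifacts. Gene ids are synthetic (`G000001` …) with no mapping to real
symbols.

## Problem sizes and numerical choices

Test and example runs use deliberately scaled settings — panels of 10–100
genes, populations of 16–80, 4–20 generations, 2–3 repeats, reduced 2×2 to
8×8 grids — chosen so each property is exercised at a size where its
expected behavior is analytically or statistically checkable. The
structural bookkeeping (records = repeats × generations, chromosome length
= panel size) is scale-invariant, which is what the acceptance script
verifies at the canonical 10 × 200 repeat/generation counts. Full-scale
cohort runs (31×31 grid, 100-gene panels, hundreds of samples) are
offline-scale computations by design.

Other numerical choices, gathered in one place: ranking ties break by gene
id; argmax ties everywhere resolve to the lowest index; dedup keeps the
first-encountered record (fitness is identical by determinism); fold
assignment is stratified round-robin after a seeded within-class shuffle;
all child seeds derive from one master seed, and every public entry point
restores the caller's RNG state.

## Known limitations

- **Fitness saturation on easy tasks.** When classes are separable enough
  that many random gene subsets already reach perfect cross-validated
  fitness, selection loses its gradient: elites lock early (ties never
  displace an incumbent), archives are dominated by assorted near-random
  dense chromosomes, and selective scores discriminate planted from null
  genes only weakly (they remain statistically higher, but rarely cross
  the ≥2 threshold). This is a property of wrapper selection itself, not of
  the implementation; the interesting regime is the hard one, where
  cross-validated performance stays below the ceiling.
- The two-class design is fixed; multi-class phenotypes must be binarized.
- Enrichment screening reports raw running-sum scores without permutation
  significance.
- The SMO iteration cap trades exactness in the flat-kernel grid corner
  for speed (see above); set `max_iter` high for solver-exact archives.
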