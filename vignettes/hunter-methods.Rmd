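---
title: "Hub-attachment module detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-attachment module detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hunter)
```

## The probabilistic network model

`hunter` models a PPI network as an undirected simple graph whose edge
weights `w(e) ∈ (0,1]` are interaction probabilities: the confidence that a
reported interaction is real. Two assumptions drive the algorithm. First, a
functional module induces a dense region of the interactome, so candidate
modules should be *reliably* dense — dense even after accounting for edge
uncertainty. Second, proteins of one complex tend to be co-expressed, so
expression incoherence between interacting proteins is evidence against a
true functional link.

Reliable density is formalized as **q-connectivity**: a vertex set `S` is
q-connected when every bipartition `(U, S−U)` is crossed by at least one
true interaction with probability at least `q`, i.e.
`1 − Π_{e crossing} (1 − w(e)) ≥ q`. Checking all `2^{|S|−1} − 1`
bipartitions directly is exponential, but taking logs turns the worst
bipartition into a global minimum cut with capacities `−log(1 − w(e))`: `S`
is q-connected iff its min-cut value is at least `−log(1 − q)`. The package
uses an exact global min cut (`igraph::min_cut`, Stoer–Wagner class); the
exponential enumeration survives only as the independent oracle in the test
suite, where it and the min-cut decision agree on hundreds of random
weighted graphs of up to 10 vertices.

### Seeds, growth, merging

For each vertex `v`, each connected component of the subgraph induced on
`N(v)` is cleaned by the **Bad Module Seed Index**: `BMSI(S, u)` counts the
members of `S` whose expression correlation with `u` is `≤ t`. The member
with the largest index is removed and all indices are recomputed, until all
are zero — a sequential argmax, with lexicographic tie-breaking for
determinism. From the connected components of the survivors, the largest
maximal q-connected subset becomes `MQC(v)`, and the seed is
`MS(v) = MQC(v) ∪ {v}` when `|MQC(v)| > 1`. Seeds are grown by the
neighbourhood-majority rule `2·|N(u) ∩ M| > |M|` with *batch* semantics:
every qualifying vertex is admitted against the same module size, then the
frontier is recomputed. Batch admission matters — two candidates each
adjacent to 2 of 3 seed members both join in one iteration, whereas
sequential admission would raise the bar for the second; the test suite
pins this distinction on a hand-traced fixture. Grown modules are kept only
if they are weak communities, then merged pairwise whenever twice the
overlap exceeds the smaller module, largest-overlap-ratio pair first, to a
fixpoint.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 0.95 | per-bipartition reliability of a seed; 0.05 "error probability". Larger values fragment seeds, smaller ones admit unreliable cores. |
| `t` | `"auto"` | expression-correlation threshold; `auto` selects it from the data (below). |
| grid | 0.6–0.99 step 0.01 | candidate cutoffs for `t`; correlations below 0.6 are treated as uninformative for co-expression. |
| `n_null` | 5 | degree-preserving rewirings averaged per grid point. |
| `min_size` | 3 | smallest reported module (a seed already has ≥ 3 members). |
| `alpha` | 1e-4 | raw enrichment cutoff in the F-measure and gold-standard matching; no multiple-testing correction by default, with an optional Bonferroni flag. |

### Threshold selection

With `r` profiled genes, the complete correlation graph `K_r` is thresholded
at each grid point `d`; `C(K_r, d)` is the mean local clustering coefficient
of the resulting graph `H` and `C_0(K_r, d)` its mean over degree-preserving
random rewirings of `H` (double-edge swaps, 10·|E| attempts). Genuine
co-expression structure makes `H` more clustered than its degree-matched
null, so `t` is the grid point maximizing `C − C_0`, with ties broken toward
the smaller cutoff (the more inclusive filter). Averaging several null
replicates rather than using a single realization reduces the variance of
the gap estimate at small `r`. Edges whose endpoint correlation is `≤ t`
are then removed — the same at-or-below convention as the BMSI — so the
boundary case `corr == t` is always treated as incoherent.

## Numerical and degenerate-input policies

* **Weight-1 edges.** `−log(1 − w)` diverges at `w = 1`; capacities are
  clamped at 745 (≈ −log of the smallest normal double), so any cut
  containing a certain edge passes every `q < 1`.
* **Zero-variance profiles.** Pearson correlation is undefined; it is taken
  as 0 with a warning, which can never pass a grid cutoff ≥ 0.6.
* **Unweighted networks.** All weights default to 1, every connected set is
  q-connected, and `MQC(v)` degenerates to the whole cleaned component.
* **Vertices of degree < 2** contribute 0 to the clustering-coefficient
  mean (Watts–Strogatz convention); `exclude_deg1 = TRUE` switches to
  averaging over degree ≥ 2 vertices only.
* **Duplicate edges** keep the maximum score (probabilities: the
  conservative choice for q-connectivity); self-loops are rejected.
* **Ties** are broken lexicographically throughout (BMSI removal, MQC
  selection, merge pair order), so identical inputs and seeds give
  byte-identical clusterings.

## Design choices where the design was open

* **Threshold rule.** Both curves `C` and `C_0` are computed on the stated
  grid; the package commits to `t = argmax (C − C_0)` with ties to the
  smaller cutoff, the natural reading of a systematic-threshold criterion
  based on comparing the observed clustering coefficient with a
  degree-matched null. Whether the null should be one realization or an
  average is equally open; averaging is strictly lower-variance.
* **Weak community.** The Radicchi *weak* definition (Σ internal degree >
  Σ external degree) on unweighted topology, applied once, after growth
  completes; failing modules are dropped, not reverted to their seeds, and
  dropped seeds are not recycled. A weighted variant is available behind
  `weighted = TRUE`.
* **F-measure.** "Weighted average of sensitivity and specificity" is
  implemented as the harmonic mean — the standard F-measure. The term
  universe for sensitivity is the aspect's terms with `1 ≤ M < N`:
  universal terms (the root) have an upper-tail p-value of 1 by
  construction and would only deflate sensitivity without carrying
  information.
* **Protein-pair similarity.** The Schlicker relevance similarity of two
  *terms* is lifted to proteins by the best-match average over the two
  proteins' direct annotation sets (`method = "max"` switches to the
  single best term pair). Direct rather than propagated sets keep the BMA
  from being dominated by shared shallow ancestors.
* **Co-localization normalization.** `Σ_j max_k |C_j ∩ O_k| / Σ_j |C_j|` —
  the fraction of clustered proteins co-localized with their cluster's
  plurality location; proteins with no localization data stay in the
  denominator.
* **Average similarity of a collection** pools all within-set annotated
  pairs (pair-count-weighted mean of per-set means).
* **Maximality of `MQC(v)`** is maximum *cardinality* (ties to the
  lexicographically smallest set), and q-connectivity is evaluated on the
  subgraph induced by the cleaned component alone, not component ∪ {v}.
* **Enrichment background.** `N` defaults to the annotated proteins of the
  chosen background (the input network's proteins when supplied); absolute
  p-values shift with this choice, so it is exposed as the `background`
  argument.

## What the synthetic benchmark emulates — and what it does not

The planted-module generator produces the statistical structure the
algorithm assumes: modules as dense blocks of high-confidence edges
(density 0.9, weights 0.9–0.99 in the `easy` preset, with a forced spanning
path so every planted module is connected), a sparse low-confidence
background (density 0.01, weights 0.1–0.5), co-expression as a shared
latent profile per module observed with Gaussian noise calibrated as
`noise_sd = sqrt(1/ρ − 1)` for a target within-module correlation ρ (0.9 by
default, 20 conditions), anticorrelated decoy edges emulating false
positives, and nested annotation coherence (per-module leaf terms, optional
deeper core terms) for the evaluators. The `overlap` preset shares 10% of
vertices between consecutive modules to exercise the merge stage.

It deliberately does **not** mimic a real interactome's degree
distribution, the empirical shape of confidence-score distributions, hub
proteins spanning many complexes, condition-dependent expression, or the
depth and redundancy of the real Gene Ontology. Passing the planted-recovery
tests therefore shows the machinery is correct under the model's own
assumptions, not that the defaults are optimal for any particular organism's
data.

Problem sizes in the test and acceptance runs are chosen so the whole suite
executes in well under a minute of compute per file: benchmarks of ~90–110
vertices, q-connectivity oracles on ≤ 10-vertex graphs (500 replicates),
hypergeometric cross-checks for all `N ≤ 25`, and 20 independent seeds for
the nested-coherence ordering. All generators thread a single integer seed,
so every number in the acceptance report is reproducible.

## Known limitations

* Seed construction visits every vertex and solves min cuts on its cleaned
  neighbourhood; on networks with very large dense neighbourhoods
  (thousands of members) the recursive min-cut splitting is the dominant
  cost. The algorithm remains exact; it is simply not tuned for
  interactomes orders of magnitude denser than typical yeast-scale data.
* Pearson correlation is the only co-expression measure; rank-based or
  information-theoretic measures are out of scope.
* The evaluators score what is annotated: proteins without GO annotation
  are invisible to similarity scores (though they still count in cluster
  sizes for co-localization), and results inherit the biases of the
  annotation corpus supplied.
* Merging does not re-test weak-community status of merged unions; on
  pathological overlap structures a merged module can in principle fail
  the criterion its parts satisfied.

```{r example}
sim <- simulate_preset("easy", seed = 7)
cl <- run_pipeline(sim$net, sim$expr, seed = 7)
length(cl$modules)
best_jaccard(cl, sim$truth)
```
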