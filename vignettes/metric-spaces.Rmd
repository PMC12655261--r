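---
title: "Metric-space chain representations for druggability prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-space chain representations for druggability prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugspace)
```

## The model

`drugspace` treats druggability prediction as classification in metric
space rather than in feature space. A protein chain is never reduced to
a single Euclidean vector; instead, four biologically motivated
distances are defined directly between chains, and a k-nearest-
neighbour classifier operates on each precomputed distance matrix. The
four base predictions are fused by majority voting, with a continuous
ensemble score (the mean positive-neighbour fraction) retained for ROC
analysis.

The underlying assumptions, feature by feature:

* **Hydropathy.** The distribution of hydrophobic and hydrophilic
  stretches constrains folding and assembly, so two chains with
  well-alignable Kyte–Doolittle profiles are treated as structurally
  related. Because the functionally relevant region of a binder is
  unknown, the whole chain is compared at its best window alignment:
  the shorter profile slides along the longer one and the minimum
  windowed mean absolute difference is taken. This is deliberately an
  optimistic (best-local-match) comparison, not a global alignment.
* **PTM density.** The linear density of modification sites reflects
  domain organisation; chains are summarised by seven per-type
  densities (six PTM classes plus the USP domain) normalised by the
  *effective length* — the most terminal annotated site position —
  so that unmodified terminal segments do not dilute the signal.
* **PTM distribution.** Beyond abundance, the positions of
  modifications along the chain carry local-structure information.
  Per-type ascending relative positions are compared by dynamic time
  warping, which tolerates insertions and non-uniform shifts. A type
  absent from one chain is represented by a pseudo-position of 2,
  outside the normalised range, so absence itself is evidence of
  divergence.
* **Secondary structure.** The helix/strand/turn/coil composition is a
  point on the 4-simplex; the L1 norm measures total compositional
  divergence and is bounded by 2.

None of these distances is claimed to be individually decisive. The
design bet is complementarity: each captures a different axis of
structural similarity, their error profiles decorrelate, and majority
voting converts that diversity into robustness.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window stride `step` | 2 | residues | halves the offset grid versus stride 1 at negligible cost in alignment quality |
| positional weights `weights` | all 1 | — | no position is privileged a priori; hook for motif-weighted variants |
| norm order `norm_order` | 1 | — | L1 avoids over-penalising a single large deviation and keeps the score interpretable as a mean absolute difference |
| normaliser `normalizer` | shorter-chain length | residues | makes window costs comparable across chain-length pairs |
| pseudo-position | 2 | relative units | outside [0, 1] so an absent type costs at least 1 against any real site, yet never dominates the 7-type sum |
| KNN size `k` | 5 | chains | odd (no within-model vote ties); small enough for a 36-positive class; the neighbour diagnostics analyse ranks 1–5 |
| k-means restarts | 10 | — | the 4-dimensional L1 objective has local optima; restarts with a seeded RNG keep the fit deterministic |
| permutations `m` | 1000 | — | attainable significance floor (b = 0) is p = 1/1001 < 0.001 |

## Numerical and procedural choices

* **Offset grid.** Window offsets run over t = 0 … ⌊(|c_j| − |c_i|)/s⌋.
  When the length difference is odd the terminal alignment is *not*
  force-included; the index set is taken literally, and the brute-force
  oracle in the tests enumerates the same grid.
* **Symmetry by construction.** The sliding-window distance orders its
  arguments (shorter, longer) internally; equal lengths collapse the
  grid to the single offset t = 0.
* **Site centres.** An interval [a, b] is represented by
  ⌊(a + b)/2⌋ — the centre is defined as a residue index, so
  half-integer midpoints are floored.
* **Zero-PTM chains.** Effective length falls back to the full sequence
  length. The density vector is all-zero either way; the fallback only
  guards the division.
* **Overlapping sites.** Duplicate or overlapping sites of one type
  each count once toward density and contribute one relative position
  each; no merging is performed, since the annotation source, not the
  package, owns that semantics.
* **Multi-site absence.** When a type with several sites meets an
  absent type, the DTW against the one-element pseudo-sequence [2]
  yields the sum Σᵢ |rᵢ − 2| — the DTW-consistent generalisation of the
  single-site penalty. Both-absent types cost |2 − 2| = 0.
* **Tie-breaks.** Neighbour ties at the k-th rank are resolved
  lexicographically by chain id; a 2–2 ensemble vote is resolved by the
  mean positive score against 0.5 (≥ 0.5 → positive); distance-tied
  Algorithm-1 rescues take the first chain in id order. Every path
  through the pipeline is deterministic given its seed.
* **Cluster polarity.** The cluster mapped to "druggable" is the one
  *enriched* for chains from positively annotated complexes (largest
  fraction of its members), not the one holding the largest raw count:
  positive complexes also contribute their non-druggable partner
  chains, which under class imbalance would otherwise swamp a count
  rule. An exact tie goes to the smaller cluster, keeping positives
  rare.
* **Labelling before evaluation.** Clustering and the correcting
  algorithms run once on the full dataset before cross-validation, and
  permutation replicates shuffle the fixed label vector without
  re-running the labelling. This mirrors the study protocol the package
  implements; the `apply_corrections` flag exposes the raw-clustering
  arm for the ablation.
* **Confidence score.** The diagnostics' distance-based confidence
  1/(1 + mean k-NN distance ÷ median pairwise distance) is a package
  convention: normalising by the per-metric median makes the score
  comparable across metrics living on very different scales (hydropathy
  distances are an order of magnitude larger than simplex distances).
  A degenerate all-zero matrix defines confidence as 1.
* **Precision on empty positives.** If a model predicts no positives,
  precision is reported as 0 with an explicit flag and warning rather
  than NaN.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws chains per class: sequences from
class-biased residue frequencies plus a hydrophobic motif in positives
(hydropathy signal); secondary-structure proportions from
class-conditional Dirichlet distributions with concentration 30 (SS
signal, and the substrate for the labelling clustering); per-type PTM
counts from class-conditional Poisson rates, positions from a clustered
point process (Beta-distributed cluster centre plus Gaussian jitter)
converted to intervals of 3–8 residues (density and DTW signals).
Chains are packed into complexes of 1–4 chains; each positive chain
anchors a positive complex with up to three negative partners, and a
configurable fraction of positives receives deliberately ambiguous SS
profiles to exercise Correcting Algorithm 1. A single scalar
`class_separation` interpolates every class-conditional parameter
between the pooled value (0: the null model used for calibration) and
full separation (1); per-family switches allow datasets where only one
metric is informative.

Defaults follow the dataset structure the method targets: 36 positive
and 106 negative chains, sequence lengths 40–120, binary labels with
class imbalance. The generator targets *statistical* structure only: it
does not emulate sequence homology, real PTM sequence motifs,
correlations between secondary structure and sequence, or annotation
noise. Consequently, passing tests demonstrate that the implementation
recovers planted signal of the assumed form and is well calibrated
under the null — they do not certify performance on real proteins,
where the class-conditional distributions are unknown and the feature
families are correlated.

## Problem sizes used by the checks

The test suite runs the oracle comparisons on 500 random pairs each
(DTW against exhaustive warping-path enumeration at lengths ≤ 6;
sliding-window against full offset enumeration at lengths ≤ 30; metric
axioms on 500 random chain pairs), the correcting-algorithm
postconditions on 1000 random complex configurations, label recovery on
full-size (142-chain) datasets with the separation sweep averaged over
10 seeds, and permutation calibration on 50 null datasets at m = 99 —
sizes chosen to give the property tests real coverage while keeping a
full run comfortably interactive.

## Known limitations

* The hydropathy metric is not a true metric in the mathematical sense
  (the triangle inequality is not guaranteed by the windowed minimum);
  KNN only requires a meaningful dissimilarity, which is what the
  package tests assert (identity, symmetry, non-negativity).
* Labels produced by clustering-plus-correction use complex-level
  annotations that the evaluation also sees; the package replicates
  this protocol faithfully and exposes the correction flag, but the
  leakage question is inherent to the design, not resolvable here.
* Baseline featurizers implement the classical PseAAC-style correlation
  factors with a documented property set (Kyte–Doolittle hydropathy,
  Hopp–Woods hydrophilicity, side-chain mass, isoelectric point,
  Grantham polarity, standardized over the 20 residues); they are
  comparison scaffolding, not a re-derivation of any published
  benchmark's exact configuration.
* The USP domain category is treated exactly like a PTM class in both
  density and DTW metrics; domain instances and modification sites are
  not distinguished.

## A minimal end-to-end run

```{r example, eval = FALSE}
ds   <- generate_dataset(generator_config(), seed = 42)
mats <- pairwise_matrices(ds)
fit  <- loocv(ds, mats)
glance(fit)

permutation_test(ds, mats, m = 200, seed = 42)
ablation_suite(ds, mats, seed = 42)

autoplot(fit)                              # ROC curve
plot_distance_distributions(mats, ds$labels)
```
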