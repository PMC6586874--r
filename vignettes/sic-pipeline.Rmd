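---
title: "Subset identification and characterization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset identification and characterization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicflow)
```

This vignette explains the statistical machinery behind `sicflow`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic tests do and do not demonstrate about real
cytometry data.

## The problem

Given event × channel matrices from one or more cytometry samples, we
want to (1) partition each sample's events into cell populations without
user-set parameters such as the number of clusters, (2) align the
populations between two samples — including the awkward cases where one
population of sample A appears as two clusters in sample B (a *split*) or
has no counterpart at all (*missing*) — and (3) display the cluster-level
structure in two dimensions. All three stages deliberately avoid density
estimation in more than two dimensions: pairwise projections and binned
summaries keep every estimate in a regime where the available events are
sufficient.

## Display transform

Raw fluorescence values are mapped to display scale with the Logicle
transformation: logarithmic for large signals, smoothly linear through
zero, so compensated populations with slightly negative values stay on
scale and symmetric. The implementation uses the standard biexponential
parameterization with top of scale `T` (default 262,144), `M = 4.5`
decades, `A = 0` extra negative decades, and per-channel linearization
width estimated as `W = max(0, (M − log10(T/|r|))/2)` from the 5th
percentile `r` of the channel's negative values — the common default in
this field's software; the source data give no transform parameters, so
these are package choices, all overridable through `sic_config()`.
Channels whose names match `^(fsc|ssc|time)` are linearly rescaled to
`[0, M]` instead: scatter and time are not fluorescence measurements.
`logicle()` inverts the closed-form biexponential by Newton iteration
seeded from a monotone interpolation grid; the inverse is exact to
`1e-6 * T` over the full display range.

## Density-based 2D clustering

Each 2D projection is clustered by a simplified density-based-merging
scheme:

* **Density estimate.** Events are binned on a 128 × 128 grid spanning the
  data range padded by three bandwidths; the counts are smoothed with a
  separable Gaussian kernel using Silverman's rule-of-thumb bandwidth per
  axis (`stats::bw.nrd0`). Binning keeps the cost independent of event
  count; the result is normalized to a proper density.
* **Mode seeking.** Every cell hill-climbs to its density mode through its
  steepest 8-neighbour; basins of attraction are candidate clusters.
* **Mode significance.** The published density-based-merging method uses a
  statistical significance test to decide which modes are real. This
  package replaces it with two transparent geometric rules, applied
  iteratively to adjacent basin pairs until neither fires:
  * *saddle rule* — merge when the highest saddle density between two
    basins exceeds `dbm_theta` (default **0.85**) of the lower peak;
  * *prominence rule* — merge (or dissolve, for isolated noise islands)
    any mode whose topographic prominence is below `dbm_prominence`
    (default **0.05**) of the global peak.

  The saddle threshold is calibrated on the smoothed-density scale. For
  two equal Gaussians separated by `s` standard deviations the population
  saddle-to-peak ratio is approximately `2·exp(−s²/8)`; kernel smoothing
  at the Silverman bandwidth raises the observed ratio by roughly 0.05 to
  0.15. θ = 0.85 therefore splits equal mixtures separated by about 2.9 SD
  or more and merges anything closer — in particular it must, and does,
  split 3-SD-separated subpopulations while merging 0.5-SD ones. The
  prominence rule absorbs the kernel estimate's low-density wiggles
  (measured amplitude ≲ 3% of the peak at 10⁴ events), which would
  otherwise survive the saddle rule as spurious fringe clusters.
* **Outliers.** Cells below `1e-4` of the peak density are initially
  unclustered; their events are then assigned to the cluster of the
  nearest clustered event, so every event ends up labelled.

## The projection-pursuit recursion

`epp()` evaluates all unordered channel pairs — axis-aligned projections
only; arbitrary linear projections would enlarge the search space
enormously for little gain on gated cytometry channels, and the field's
gating displays are axis-aligned anyway. For every projection whose
clustering has two or more clusters, candidate two-way splits are every
cluster-versus-rest assignment plus every bipartition whose sides are
connected in the basin-adjacency graph. Each candidate is scored by the
**boundary misclassification index**: the two sides' densities are
re-estimated on a shared grid and the overlap
`Σ min(π₁p̂₁, π₂p̂₂)·cell_area` — the estimated Bayes error of the
two-class problem — is the index. The globally smallest-error candidate
wins; ties break lexicographically by channel pair, and side 1 is the
side holding the lowest-index event, which makes the recursion fully
deterministic.

A split is accepted only if its error is at most `max_error` (default
**0.10**) and both sides have at least
`max(200, 0.2% of the sample)` events. Two remarks on `max_error`:
when the sides come from the hard basin partition the overlap index
measures kernel-tail leakage across the cut (a clean valley cut of two
3-SD Gaussians scores ≈ 0.03, far below the closed-form component overlap
of 0.067), so 0.10 is a permissive guard against ragged boundaries rather
than the primary stopping rule — the mode-merging thresholds above are
what actually ends the recursion. When the sides are overlapping point
sets (e.g. ground-truth component labels in the tests), the same
estimator recovers the closed-form Gaussian overlap (Φ(−1) for 2-SD
separation) to within the kernel smoothing bias.

Recursion proceeds depth-first until no projection offers an acceptable
split; leaves are numbered in discovery order. Since `k` channels yield
`k(k−1)/2` projections per node, the exhaustive search is comfortable up
to ~20 channels.

## Adaptive binning and the quadratic-form score

To compare two samples, their events are merged and recursively halved at
the median of the highest-variance dimension (ties on the threshold go
right), to a globally uniform depth

`L = round(log2(n_merged / (2 ln N)))`, `N = min(n_A, n_B)`,

so `B = 2^L` bins hold on average about `2 ln N` events each. A uniform
depth (rather than per-branch adaptation) keeps the bin index space
shared and the tree balanced; empty bins are retained with frequency zero
and inherit their nearest non-empty ancestor's centroid. Each cluster
becomes a frequency vector normalized by *cluster* size — the score of a
matched pair then reflects shape, not abundance, which is what makes a
half-split cluster score visibly worse than a whole one.

The quadratic-form dissimilarity weights bin-frequency differences by the
similarity matrix `A_ij = 1 − d_ij/d_max` built once per binning from the
bin-centroid distances; it is a metric on the simplex for full-rank `A`
(verified property-style in the tests) and is sensitive to mass moving
*between distant bins*, unlike bin-wise distances. The degenerate `B = 1`
binning makes every score zero; matching then falls back to
median-distance ordering with a warning.

## Matching, merging, split-versus-missing

`qfmatch()` bins the two full samples once, scores every cluster pair
whose medians lie within `gate_mult = 4` standard deviations per
dimension (the per-dimension scale is the larger of the two SDs — a
conservative reading; zero-SD dimensions compare exactly), and accepts
the globally smallest scores greedily one-to-one. Greedy matching rather
than an optimal assignment mirrors the method's published description and
makes each accepted score interpretable in isolation; the candidate table
is kept in the result for inspection.

Each unmatched cluster `c` is then tested for merging: for every
counterpart `x` it was scored against, all combinations of `c` with
`x`'s current partner (always included, so every cluster stays accounted
for exactly once) and other unmatched candidates are pooled and re-binned
into a single frequency vector; if the best pooled score undercuts `c`'s
own initial score against `x` (strictly), `x` is declared *split* into
that group, otherwise `c` is *missing*. Combinations are enumerated
exhaustively up to `merge_cap = 1024`; beyond that a nearest-median
pre-filter keeps the ten most plausible partners, which leaves small
candidate sets (the realistic case) untouched.

## Displays

*MDS.* Classical (Torgerson) scaling of the pooled cluster medians —
deterministic, exact for configurations that are intrinsically planar,
and cheap because only one point per cluster is embedded. The axes are
ordered by eigenvalue and signs fixed so the first cluster has
nonnegative coordinates, making repeated runs identical. Circle radius is
the square root of cluster frequency, so circle *area* tracks abundance.
An iterative stress-majorizing MDS was considered and rejected: it adds a
random initialization for no benefit at these problem sizes.

*QF-tree.* Bottom-up agglomeration of one sample's clusters under
`QF + c·DM`. The scale factor `c` is fixed once from the initial tables
as `min(QF) / max(DM)` — the literal reading of "same order of
magnitude" — and is *not* re-derived per level, so heights remain
comparable across levels. Merged groups are pooled and re-binned pairwise
at every level, as the method treats them "as one cluster". Because the
dissimilarity is recomputed per level it is not guaranteed monotone;
violations are clamped to the running maximum with a warning (observed
magnitude ~1% on the canonical fixture). Newick exports carry the QF
component of each merge as both child edge lengths, matching the display
convention that edge length encodes the quadratic-form score.

## The synthetic generator

`simulate_pair()` draws diagonal-covariance Gaussian mixtures with fixed
seeds (Mersenne-Twister, inversion sampling), restoring the session RNG
state afterwards. `canonical_pair_specs()` is the canonical scenario:
3D; Sample A = three components (8,000/6,000/6,000 events) with pairwise
mean separation ≥ 8 SD; Sample B = four components (7,500/6,500/3,000/
3,000) where B1 and B2 sit exactly on A1 and A2 and B3/B4 straddle A3's
mean 3 SD apart. Event totals of 2 × 10⁴ per sample keep every stage —
including 20-seed replication studies — inside a few minutes on one CPU
while leaving per-bin and per-cell counts in the asymptotic regime the
method assumes. The expected alignment (two plain matches plus one split)
is recorded in the spec metadata, so tests assert against construction
rather than frozen numbers.

What the generator does *not* emulate: spectral spillover and
compensation artefacts, doublets and debris, acquisition drift, heavy
tails and skew of real fluorescence distributions, and correlated
covariance within populations. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its stated model — clean
recovery of well-separated modes, correct split/missing decisions at
3-SD substructure — not robustness to instrument artefacts; on real data
the transform and pre-gating upstream carry that burden.

## Numerical and degenerate-input choices

* Density grids are normalized to integrate to one exactly; the KDE noise
  floor motivates the prominence rule above.
* `adaptive_bin` floors `L` at 0 (samples of one event yield a single
  bin); variance ties pick the lowest dimension; threshold ties go right.
* `qf_distance` clamps tiny negative round-off inside the square root.
* Zero-variance axes raise a degenerate-axis error rather than producing
  a silent zero-bandwidth estimate.
* All tie-breaks (projection order, candidate order, greedy score ties,
  agglomeration ties) are lexicographic, making every stage deterministic
  for fixed input and configuration.
* FCS output is single-precision (the format's float type); round-trips
  are exact to float32 resolution.

## Known limitations

* Axis-aligned projections only; a rotated separating direction that no
  channel pair shows will be missed.
* The misclassification index is a density-overlap estimate, not the
  published significance machinery; its absolute scale depends on whether
  sides overlap spatially (see above).
* Matching is pairwise; aligning three or more samples requires a chosen
  reference.
* Cluster identities are numbers, not cell-type names; annotation remains
  the analyst's task.
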