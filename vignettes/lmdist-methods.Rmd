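---
title: "Methods: graph-geodesic adjustment of saturated beta-diversity measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-geodesic adjustment of saturated beta-diversity measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdist)
```

## The problem

Community dissimilarity measures with a bounded range — Bray–Curtis and
Jaccard are confined to [0, 1] — cannot distinguish "far" from "very far".
Along a long environmental gradient with high species turnover, any two
samples separated by more than a few species' niche widths share almost no
features and land near the bound together. The pairwise distance
distribution then piles up at its upper end (left skew), and ordination
bends the gradient into an arch or horseshoe because the measured geometry
is no longer compatible with a line. Unbounded metrics (Euclidean,
Aitchison, UniFrac) saturate the same way once feature overlap vanishes.

The local view, however, is still trustworthy: samples close on the
gradient share many species and their dissimilarities are informative. The
adjustment implemented here exploits exactly that asymmetry.

## The transform

Given a distance matrix $D$ and a neighborhood radius $r$:

1. **Neighbor graph.** One node per sample; an undirected edge of weight
   $D_{ij}$ for every pair with $0 \le D_{ij} < r$ (strict inequality; a
   pair at exactly $r$ is excluded). A pair at distance exactly 0
   (duplicate samples) gets a zero-weight edge so duplicates remain
   mutually at distance zero.
2. **Connectivity repair.** Uneven sampling or a small radius can fragment
   the graph. A minimum spanning tree is computed on the complete graph
   weighted by $D$, and precisely those MST edges whose endpoints lie in
   different components are added (one fewer than the number of
   components). They are flagged as borrowed: they exceed the radius but
   are the minimal set of long edges we are forced to trust.
3. **Geodesics.** Every pairwise value is replaced by the shortest-path
   length between the two nodes (Dijkstra from each source; all weights
   nonnegative). The result is a path-length metric — symmetric, zero
   diagonal, triangle inequality — and values may exceed the original
   measure's bound.

Two consequences worth knowing. First, for a *metric* input and $r$ above
the largest distance the transform is the identity, and shrinking $r$ can
only lengthen geodesics (entries are elementwise non-increasing in $r$) —
both properties are exercised in the test suite. Second, Bray–Curtis is
only a semimetric: where it violates the triangle inequality, a two-hop
path can be genuinely shorter than the direct edge, so a few *small*
distances may shrink. This is accepted behavior — the output must be a
metric — and is documented rather than suppressed.

## Automatic radius selection

The radius is the only tuning knob that matters, and it is chosen without
reference to any metadata.

* **Candidate grid.** `n_radii` (default 50) evenly spaced values from just
  above the smallest positive distance up to and including the largest.
  The even full-range grid is our own choice; it exposes both regimes (a
  near-maximal radius barely changes the matrix, a small one adjusts
  heavily).
* **Degree filter (`phi`, default 0.10).** A radius whose graph has average
  degree below `phi * n` is discarded: with almost no trusted edges the
  geodesics run along near-MST paths, which overfits the particular sample
  set and exaggerates distances. Borrowed MST edges are deliberately *not*
  counted in the degree — they exist at every radius, so counting them
  would mask exactly the sparsity the filter is meant to detect.
* **Objective.** For each surviving radius, the adjusted matrix is embedded
  by PCoA, truncated to the smallest number of axes exceeding 80%
  cumulative variance (at most 10), and scored by the Pearson correlation
  between adjusted distances and Euclidean distances among the embedded
  points. A saturated matrix embeds poorly (the arch spreads one gradient
  over several axes); the score rises as the adjusted geometry becomes
  representable in few dimensions. Pearson is used throughout for
  consistency with the axis–gradient correlations reported elsewhere.
* **Selection rule (`epsilon`, default 0.05).** Walking the grid from the
  largest radius down, the first valid radius is the incumbent; a smaller
  radius displaces it only if its score exceeds the incumbent's by more
  than `epsilon`. The asymmetry is intentional: larger radii trust more of
  the original data, so a smaller radius must earn its keep. With
  `epsilon = Inf` the largest valid radius always wins; with `epsilon = 0`
  the rule reduces to argmax with ties going to the larger radius.
* **Smoothing (off by default).** Instead of trusting one radius, the
  adjusted matrices of all valid radii can be averaged with Gaussian
  weights centered at the chosen radius. The default width is one tenth of
  the grid span, which makes roughly the two neighboring grid radii on
  each side influential without flattening the average. The result is a
  convex combination, so it stays within the elementwise envelope of its
  inputs.

Degenerate inputs are handled conservatively: with fewer than 4 samples
(PCoA fidelity is meaningless), or when no radius passes the degree filter,
no adjustment is performed and the input is returned with
`chosen_radius = NULL`.

## When should a matrix be adjusted?

`oversaturation_check()` computes the adjusted Fisher–Pearson skewness of
the off-diagonal distances. Saturation produces a *left* skew (mass near
the upper range, thin left tail); the boolean verdict uses a cutoff of
−0.1, a pragmatic default chosen because "clearly negative" is the
scientifically meaningful condition — the numeric skewness is always
returned so users can judge for themselves. Clustered case–control data
typically shows a right skew, and on such data the selection rule keeps the
largest valid radius, leaving the matrix essentially untouched (the test
suite checks a two-blob simulation changes by under 1% on average).

## The simulated gradient community

`simulate_coenocline_community()` builds the validation dataset used
throughout the tests: species response curves are Gaussian coenoclines of
common SD 150 on a gradient of length 1000 (arbitrary units), with optima
every 10 units. Optima extend 650 units past both gradient ends, which
serves two purposes: edge samples see an untruncated species pool, and the
pool size comes out at $(1000 + 2 \cdot 650)/10 + 1 = 231$ features for the
default geometry. A sample at position $x$ collects every species' density
at $x$ and is closed to relative abundance; 50 samples sit evenly on the
gradient. `add_dirichlet_noise()` then draws one noisy replicate per sample
from a Dirichlet distribution whose concentration vector is the parent
composition times `dirichlet_scale` (default 500, giving visible scatter
while keeping replicates near their parents; concentrations are floored at
1e-12 so species far from a sample cannot zero out the distribution). Noise
samples inherit the parent's gradient position.

What the generator emulates: smooth unimodal turnover, heavy neighbor
overlap, compositional closure, and sampling noise that respects
compositionality. What it does not: sequencing-depth/count noise, zero
inflation, uneven sampling along the gradient, and multi-dimensional
environmental structure. Passing tests on this generator therefore
demonstrate the geometry-recovery behavior of the transform, not robustness
to every artifact of real sequence data.

With the defaults, Bray–Curtis on the 100 samples is left-skewed
(skewness ≈ −0.36) and axis 1 of a direct PCoA correlates with the true
positions at |r| ≈ 0.966; after adjustment at radius 0.4 the correlation is
≈ 0.9998. `scripts/acceptance.R` recomputes both numbers over 10 seeds.

## The Swiss roll, and a note on radius scale

`swiss_roll()` draws the standard benchmark: $t = 1.5\pi(1 + 2u)$,
points $(t\cos t,\, 21v,\, t\sin t)$ with $u, v$ uniform on [0, 1]. Its
intrinsic coordinates are $(t, 21v)$. The roll is a stress test: Euclidean
distances cut through the spiral, so plain PCoA cannot recover $t$ on one
axis, while the graph transform can — provided the radius stays below the
spacing between successive windings, which is $2\pi$ in raw units, about
0.196 after rescaling all pairwise distances to [0, 1]. The test suite uses
radius 0.19 on the rescaled distances, derived from that geometry: any
radius above the winding gap admits short-circuit edges between adjacent
windings and the unrolling collapses. Published radii for this benchmark
depend entirely on the coordinate normalization in use, so the geometric
derivation is the portable statement. Note also that at $n = 300$ points
the non-shortcutting radii fall below the `phi = 0.10` degree filter — the
roll is too sparsely sampled for the unsupervised rule — so the benchmark
is run at a fixed radius, mirroring how manifold-learning comparisons tune
their neighborhood parameters.

## Numerical choices

* Strict `< r` edge inclusion; ties at the radius are excluded.
* MST edges are generated in lexicographic node order, making the tree
  deterministic under ties.
* PCoA drops negative eigenvalues (no Lingoes/Cailliez correction);
  variance fractions are computed over the positive spectrum. Axis signs
  follow a fixed convention (largest-magnitude coordinate positive), so
  output is reproducible; axis–gradient correlations take absolute values
  because the sign of an axis is arbitrary regardless.
* Retained eigenvalues must exceed `max(eig) * 1e-9`, which discards the
  numerically-zero round-off eigenvalues of exactly embeddable
  configurations.
* The ordination-fidelity objective returns 1 for constant-distance inputs
  whose embedding reproduces them exactly (regular simplices), and 0 with
  a warning when the embedding is genuinely degenerate.
* Distance-matrix input is validated to 1e-8 (asymmetry, diagonal) and then
  symmetrized exactly; serialization round trips are exact to ~1e-15.
* Binary (presence/absence) Jaccard is the only Jaccard mode, matching the
  classical set definition; the abundance-weighted variant is deliberately
  not offered.

## Problem sizes

The test suite and acceptance script run on the generator defaults (100
samples × 231 features, 10 seeds), 300-point Swiss rolls, and random
instances of 5–30 samples for the property checks (100 shortest-path oracle
comparisons, 50 metric fixed-point cases, 20 monotonicity grids). These
sizes fully exercise every code path; the algorithm itself is
$O(n(E + n\log n))$ per radius and handles thousands of samples.

## Limitations

* The adjustment assumes variation lies along a sampled manifold; with
  large sampling gaps the borrowed MST edges dominate and adjusted
  distances inherit their arbitrariness. The degree filter guards against
  this in automatic mode but cannot create samples that were never taken.
* Radius auto-selection needs the manifold to be sampled densely enough to
  pass the degree filter at a non-shortcutting radius (see the Swiss-roll
  note); sparse manifolds require a manually fixed radius.
* For semimetric inputs, some small distances can contract below their
  original values (triangle-inequality repair); analyses that depend on
  preserving small original dissimilarities exactly should compare both
  matrices.
* The oversaturation verdict is a heuristic cutoff on a single moment;
  borderline skewness deserves a look at the distance histogram.
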