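---
title: "Mapping single-cell fate commitment on a simplex: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-cell fate commitment on a simplex: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatesimplex)
```

## The model

A differentiating cell is modeled as a convex combination of a small set of
terminal fates. The user chooses `N` (2–4) terminally differentiated
clusters from the annotation; these anchor the vertices of an
`(N-1)`-dimensional simplex — a segment, a triangle, or a tetrahedron. The
quantity attached to each cell is a length-`N` vector of non-negative
weights summing to one: its barycentric coordinate, read as relative
affinity toward each fate. Because the weights are constrained to the
simplex, the axes of the plot carry direct biological meaning, unlike
generic 2-D embeddings whose coordinates are artifacts of the reduction.

The coordinate is built in four steps from a feature-by-cell expression
matrix `E` (RNA or ATAC counts) and the terminal-cluster centroids `V`:

1. `D[c, n] = sqrt(sum_i (E[i, c] - V[i, n])^2)` — Euclidean distance from
   cell `c` to centroid `n` in a selected feature subspace, after
   per-cell depth normalization (counts per 10,000) and `log1p`.
2. Each cell's `N` distances are divided by their sum, so all cells'
   distances live on the same unit-sum scale regardless of their absolute
   magnitude.
3. `S[c, n] = exp(-D[c, n] / σ)` maps normalized distances to similarities
   in `(0, 1]`.
4. Per vertex, similarities are range-scaled onto `[0, 1]`
   (`min -> 0`, `max -> 1`), and finally each cell's row is L1-normalized.

Step 4's range scaling is what makes the plot readable: raw kernel
similarities for different vertices can occupy very different ranges
(a tight cluster near one centroid compresses everyone else's similarity
to it), and the per-vertex affine map restores comparable dynamic range
before the final normalization.

### Assumptions

- The chosen terminal clusters are genuinely distinct expression states;
  coincident centroids are a degenerate input and are rejected.
- Affinity is monotone in centroid distance within the selected subspace;
  no cluster-shape information beyond the mean is used.
- When a transition graph is supplied, its rows are source cells and its
  edge weights are non-negative transition propensities. The package never
  infers velocity itself; it only aggregates a graph produced upstream.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `top_k` | 30 | marker genes kept per terminal fate (dimensionless count); the subspace is the union across fates |
| `sigma` | 0.08 | kernel bandwidth on the unit-sum distance scale; smaller values sharpen commitment toward the nearest vertex |
| `scale_factor` | 10,000 | per-cell depth target before `log1p` (counts) |
| `n_components` | 10 | PCA dimensionality when `method = "pca"` |
| `grid_resolution` | 10 | velocity bins per axis over the vertex bounding box |
| `arrow_max_len` | 0.15 | plot length (in simplex units) of a weight-1 arrow |

The bandwidth deserves comment. The kernel is written with a first-power
exponent, `exp(-d/σ)`, not the squared-exponential form; since the
distances entering it are row-normalized to unit sum, their scale is fixed
and a single scalar bandwidth is well-posed for every dataset. At
`σ = 0.08`, a cell with a distance profile like `(0.13, 0.43, 0.44)` — a
typical committed cell — has kernel similarities `(0.20, 0.005, 0.004)`,
i.e. ~96% of its similarity mass on its own vertex before range scaling,
while a cell equidistant from all fates stays at the center. A
per-cell or quantile bandwidth would be an alternative reading; the scalar
was chosen for transparency and is exposed as a user parameter.

## Marker selection

For each terminal fate the package runs a two-sided Wilcoxon rank-sum test
per feature, comparing that fate's cells against the cells *of the other
chosen fates* — not against all cells. The simplex contrasts terminal
fates with each other, and the centroids are computed only from terminal
cells, so the discriminative background is the other vertices; progenitor
and bystander populations never influence the subspace. The test uses
midranks, a tie-corrected variance, and a continuity correction; for group
sizes up to 6 vs 6 the approximate p-value stays within 0.09 of the
exhaustive-permutation p-value over all untied rank configurations (the
suite verifies this exhaustively). With heavy ties at such tiny sizes any
normal approximation drifts further from the exact permutation law; at
realistic cell numbers the approximation is the standard choice.

Ranking is by ascending p-value, ties broken by descending log2 fold
change (pseudocount `1e-9`), then feature id, so selection is fully
deterministic. Only positively enriched features qualify: a marker is
something a fate over-expresses. No multiple-testing correction is applied
because selection is top-`k` by rank, not thresholded by significance.

## Velocity aggregation

The fate potential of cell `c` toward terminal `n` is the mean of the edge
weights from `c` into cluster `n`, with absent edges counted as zero and
the denominator equal to the full cluster size (minus one when `c` is its
own target-cluster member, whose self-edge is excluded). Averaging over
the whole cluster rather than over connected neighbors only keeps the
score monotone in connectivity and robust to the kNN sparsification most
velocity tools apply.

For display, cells are binned into `resolution^(N-1)` axis-aligned squares
or cubes over the bounding box of the *vertex polytope* — not of the data —
so bin boundaries do not shift with the dataset; intervals are half-open
with the final bin closed. Within a bin, member potentials are averaged
first and then normalized to unit sum across fates (mean-then-normalize,
in that order), and one arrow per fate is drawn from the bin centroid
toward the vertex with length proportional to the normalized weight.
Normalization is within each bin, because arrow lengths are compared
within a bin, not across the plot.

## Numerical and degenerate-case choices

- Distances are computed via the expanded quadratic form with a clip at
  zero against roundoff; the suite checks agreement with a naive
  double-loop implementation to 1e-10.
- A constant similarity column (every cell equally similar to a vertex)
  carries no ordering information and is mapped to 0.5, with a warning.
- A cell at the columnwise minimum for every vertex has an all-zero scaled
  row and receives the uniform coordinate `1/N`, with a warning.
- An all-zero cell passes depth normalization as zeros, with a warning.
- Row sums in the normalization steps are accumulated in a canonical
  column order, so re-listing the terminals in a different order permutes
  the output columns *exactly*, not merely to floating-point tolerance.
- PCA uses centering only and fixes each component's sign so that its
  largest-magnitude loading is positive, making the embedding
  reproducible.
- Plot geometry (vertices, points, arrow endpoints, colors) is exposed as
  tibbles by `simplex_geometry()`; all plot tests assert on this layer,
  never on rendered pixels, which are brittle across graphics backends.
- Vertex projections are fixed: segment `0–1`, triangle `(0,0)`, `(1,0)`,
  `(1/2, √3/2)`, regular tetrahedron with apex `(1/2, √3/6, √6/3)`. The
  quaternary view uses an orthographic projection at azimuth 30°,
  elevation 20° by default; the camera convention is a package choice.

## What the generator emulates — and what it does not

`simulate_fate_data()` reproduces the canonical study design for this kind
of method: `N` terminal clusters, each with a disjoint block of
over-expressed markers, plus a multipotent progenitor population whose
expression is a mixture of the terminal profiles and whose transition-edge
mass into each terminal cluster is proportional to the mixture weight.
Defaults — 3 fates × 100 cells, 100 progenitors, 200 features, 10 markers
per fate with a +5 mean-count uplift over a base rate of 1, Poisson
counts, uniform mixture — give a clearly separable but noisy dataset of
the size a desk-scale validation needs; these sizes are also what the test
suite and the acceptance script run.

The generator produces integer counts and a sparse matrix, so the code
paths real droplet data exercises are stressed. It does **not** emulate
several properties of real data: gene–gene correlation structure, depth
variation across cells, ambient contamination, doublets, batch effects, or
a realistic ATAC fragment model (an ATAC run is just a second count matrix
with its own marker blocks). Passing tests on this fixture therefore
demonstrate correctness of the algorithmic chain and recovery under the
declared noise model — not robustness to every artifact of real
experiments.

The two multi-omic modalities are treated as independent runs sharing the
annotation; the package does not attempt to pair RNA and ATAC features.

## Known limitations

- At most four vertices: beyond a tetrahedron there is no faithful spatial
  chart, and the method's readability argument collapses.
- No uncertainty on coordinates or on the upstream velocity inference is
  propagated or displayed.
- Marker selection assumes each terminal cluster has at least two cells
  and meaningful within-subspace separation; indistinguishable clusters
  produce an explicit error rather than an arbitrary embedding.
- The transition graph is consumed as-is; a transposed (target-on-rows)
  matrix will silently reverse the meaning of the arrows, so orientation
  is the caller's responsibility.
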