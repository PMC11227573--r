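---
title: "Graph-based RNA-to-cell assignment without cell-shape priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based RNA-to-cell assignment without cell-shape priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comseg)
```

## The problem

Imaging-based spatial transcriptomics (smFISH, MERFISH, HybISS, ...)
detects individual RNA molecules of a marker-gene panel at sub-cellular
resolution, but does not say which cell each molecule came from.
Membrane stains that would delineate cells are often unavailable or
unreliable, and segmentation methods that assume convex or elliptic cell
shapes fail in tissues such as lung, where cells are irregular and
lacunar spaces (airways) interrupt the tissue. This package assigns
molecules to cells using only two inputs that are almost always
available: the RNA point cloud itself and nucleus landmarks from a DAPI
stain. No shape prior is used beyond two length scales — the mean cell
diameter $D$ and a maximum cell radius $R_{max}$.

## The model, step by step

**1. Proximity-weighted expression (PE).** For each molecule at position
$x$ we summarise its local transcriptomic environment as a gene-length
vector $V(x)$. Considering at most $K_{pe} = 40$ neighbours $y$ within
$R_{pe} = D/2$,

$$V_g(x) = \sum_{y \in KNN(x),\, gene(y)=g} \frac{R_{pe} - \lVert x-y\rVert}{R_{pe}},$$

a kernel that decays linearly from 1 at $x$ to 0 at $R_{pe}$, so close
molecules dominate. The anchor molecule is excluded from its own
neighbourhood; including it would add a constant to its own gene and
inflate same-gene correlations. Ties at the $K$-th neighbour distance
are broken by molecule index so results are reproducible.

**2. Co-expression matrix.** Stacking all $V(x)$ gives a molecules ×
genes matrix $V$; the gene–gene co-expression matrix is the Pearson
correlation of its columns, $w_{ij} = \mathrm{Corr}(V_i, V_j)$. Genes
whose PE column has zero variance carry no evidence and get zero
correlation with everything, including their own diagonal; these zero
weights are inert downstream. An externally derived matrix (e.g. from
scRNA-seq) can be supplied instead via `import_external_coexpression()`.

**3. Molecule graph.** Each molecule connects to at most $K_{knn} = 10$
neighbours within $R_{knn} = D/4$ (union of the directed relations).
Each edge carries both the co-expression weight $w_{g_u g_v}$ of its
incident genes and its Euclidean length in µm. Molecules lying inside
the same nucleus are contracted into a single *cell node*; weights of
merged parallel edges are summed. The lengths of edges touching a cell
node are measured from the nucleus centroid: taking the minimum of the
merged lengths instead would let a geodesic path undercut the
straight-line distance from the centroid whenever the nucleus has
spatial extent, breaking the invariant that geodesic ≥ Euclidean
distance which the assignment stage relies on.

**4. Constrained Louvain.** The graph is partitioned into RNA
communities by greedily maximising modularity

$$Q = \frac{1}{2m} \sum_{u,v} \left[ w_{g_u g_v} -
\frac{k_u k_v}{2m} \right] \delta(C_u, C_v)$$

over the positively weighted edges only (negatively co-expressed genes
are unlikely to share a cell). The single modification to classic
Louvain: two cell nodes may never end up in the same community, at any
stage of any pass, so each community belongs to at most one cell. Node
sweeps run in an order reshuffled from the seeded generator; ties in
modularity gain go to the smallest community id. After the usual
aggregation cycles converge, node-level sweeps on the original graph are
restarted from the current membership until no single-node move improves
$Q$ — the returned partition is therefore a genuine local optimum at the
molecule level, not merely at the aggregated level. With no positive
edges, $Q \equiv 0$ and the all-singleton partition is returned.

**5. In situ clustering of communities.** Each community $C$ receives
the mean PE vector of its members, $V_C = \frac{1}{\#C}\sum_{x \in C}
V(x)$. Communities of at least 3 RNAs are normalised (total-sum scaling
to the median community total, then `log1p` — the $V_C$ are continuous
kernel sums, not counts, so a simple stabilisation suffices), optionally
PCA-reduced (automatic when the panel exceeds 30 genes; at most 20
components), and clustered with Leiden (modularity objective, resolution
1.0, seeded). The clusters are the transcriptomic profile labels $L_i$;
every molecule inherits its community's label. Communities below the
size threshold take the majority label of the $K_{small} = K_{knn}$
nearest labelled molecules, ties resolved toward the single nearest one.

The graph Leiden runs on deserves a note. Up to 2000 communities we use
the *full* positively-weighted cosine-similarity graph rather than a
bare 15-nearest-neighbour graph. Near-duplicate expression vectors make
a KNN graph band-like (neighbours order along the noise manifold), and
modularity at resolution 1 then carves homogeneous profile groups into
slivers; lowering the resolution instead makes genuinely distinct
profiles merge through the few mixed communities that straddle cell
boundaries. The dense similarity graph is immune to the banding while
preserving separation between orthogonal marker profiles; beyond 2000
communities it is sparsified to the 15 nearest neighbours per node with
weights kept.

**6. Final assignment.** Every nucleus becomes a labelled centroid node:
nuclei with nuclear RNAs take their majority label; empty nuclei take
the majority label of at most $K_{centroid} = 15$ molecules within
$D/2$ (Euclidean; the radius of this vote is not specified as geodesic
anywhere, and empty nuclei have no graph attachment to measure geodesics
from); nuclei with no molecule in reach yield empty cells. A
multi-source Dijkstra then runs from all centroids with Euclidean edge
lengths, *partitioned by label*: a path may only traverse molecules
carrying the source's label, so a cell cannot tunnel through a
neighbour's territory (set `label_constrained_paths = FALSE` to relax
this). Each molecule joins the label-matching centroid with the smallest
geodesic distance; beyond $R_{max}$ it stays unassigned; nuclear
molecules always belong to their own nucleus. Ties go to the smaller
cell id. Geodesic rather than Euclidean distance is what makes the
$R_{max}$ cut-off shape-agnostic: the distance is measured along the
cell's own point cloud, around lacunae and along non-convex arms.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `D` | required | µm | mean cell diameter; sets `R_pe = D/2`, `R_knn = D/4`, `R_centroid = D/2` |
| `R_max` | `D` | µm | maximum geodesic cell radius |
| `K_pe` | 40 | — | neighbour cap of the PE kernel |
| `K_knn` | 10 | — | molecule-graph neighbours |
| `K_centroid` | 15 | — | neighbours for empty-nucleus label votes |
| `K_small` | `K_knn` | — | neighbours for small-community relabelling |
| `leiden_resolution` | 1.0 | — | Leiden resolution for profile clustering |
| `z_anisotropy` | 1.0 | — | multiplier on z before any distance |
| `seed` | 1 | — | drives Louvain sweep order and Leiden |

A practical guide for `D`: use the area-equivalent diameter of a typical
cell ($2\sqrt{A/\pi}$). The bundled benchmark conditions do exactly
this — ~16.9 µm for 15 µm square cells, ~33.9 µm for L-shaped cells of
four such squares — and set `R_max` to the farthest in-cell point from a
nucleus (15 µm and 52.5 µm respectively). Coordinates are physical µm
throughout; raster inputs are converted at read time with the supplied
voxel size, and 2D data are 3D with $z = 0$.

## The synthetic tissue generator

`simulate_grid()` builds a checkerboard of 15 µm × 15 µm cells at
0.150 µm/voxel with concentric disc nuclei of radius 3.75 µm;
`simulate_lshapes()` interlocks pairs of L-tetromino cells (four such
squares each), the nucleus at the centre of a seeded-random constituent
square — a worst case for convex-shape methods, since much of a cell is
closer to its partner's nucleus than to its own. `grow_cells()` grows
irregular cytoplasms from nucleus seeds: each cell draws a per-round
dilation probability once from U[0.5, 1] and expands its frontier by one
voxel with that probability, confined to an allowed mask (lacunae are
simply holes in that mask); contested voxels go to the first claimant in
a seeded random round order. `drop_nuclei()` erases a seeded
⌊fraction·N⌋ subset of nuclei while keeping their cells' RNAs — cells
whose nucleus was lost to the section cut. Expression uses a marker-panel
model (exclusive markers per type, negative-binomial counts, small
off-target leak) or user-supplied reference rows; counts are multiplied
by a capture factor (default 3, reflecting the gap between scRNA-seq and
smFISH capture rates) with stochastic rounding so expectations are
exact, and molecules are placed uniformly over the cell mask with
sub-voxel jitter.

What the simulations do *not* emulate: sub-cellular RNA localisation
(nuclear enrichment, transport granules), detection noise and spot
misidentification, optical crowding, z-dependent detection efficiency,
and continuous expression gradients within a cell type. Passing the
bundled benchmarks therefore demonstrates correct mechanics and the
claimed advantage on non-convex geometry, not performance on any
particular experimental dataset.

## Numerical and degenerate-input choices

* Neighbour ties are broken by molecule index; modularity-gain ties by
  smallest community id; equal geodesic distances by smaller cell id;
  label votes by the nearest labelled molecule. Everything stochastic
  flows from the single `seed`.
* Zero-variance PE columns get zero correlation (diagonal included); a
  single-row PE matrix is an error (correlation undefined).
* An edgeless positive graph has $m = 0$: modularity is defined as 0
  and Louvain returns singletons.
* A molecule inside two centroid spheres (centroid-only landmarks,
  membership radius `nucleus_radius = D/4`) goes to the nearest
  centroid; raster labels cannot overlap by construction.
* Capture-factor scaling uses floor-plus-Bernoulli stochastic rounding,
  so `factor = 3` turns a sampled count of 2 into exactly 6 while
  non-integer products remain correct in expectation.
* Cells with at most 5 molecules are excluded from cosine cell-type
  calling; zero vectors after filtering are dropped with a warning and
  orthogonal profiles tie-break to the smallest type id.

## Problem sizes

The test-suite study conditions are a 10 × 10 grid (two checkerboard
types, five exclusive markers each, ≈ 6000 molecules) and 32
interlocking L-shaped cells with 20 % nucleus dropout (three replicate
datasets, ≈ 2000 molecules each; five segmentation seeds on one of them
for the sweep-order robustness check). These sizes give each cell ≈ 60
molecules — a realistic panel-limited density — while keeping every
stage exactly reproducible from the seeds. `scripts/acceptance.R`
re-runs both conditions from scratch and reports the resulting Jaccard,
wrongly-assigned and missing fractions for this method and the
nearest-nucleus Watershed baseline, plus cell-type-calling accuracy and
the seed-robustness range.

## Known limitations

* The method stands on discriminative marker panels: if the resolved
  genes do not separate the cell types present, co-expression weights
  carry no signal and segmentation degrades toward distance-based
  assignment.
* Cells without a nucleus landmark produce no cell; their molecules can
  at best stay unassigned (the label constraint usually ensures this,
  which is why the false-discovery fraction stays low under nucleus
  dropout).
* Profile clustering uses expression only; neighbouring communities'
  labels are not used to correct isolated mislabelled communities.
* The PE/graph stages assume molecule densities where `K_pe`/`K_knn`
  neighbourhoods are informative; extremely sparse panels may need a
  larger `D`.
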