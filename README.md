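# comseg

Shape-agnostic assignment of RNA molecules to cells for imaging-based
spatial transcriptomics, in R.

Single-molecule FISH technologies (smFISH, MERFISH, HybISS, ...) deliver
point clouds of individual RNA molecules with gene identities, but not
the cells they belong to. When no reliable membrane stain exists, and
when cells are non-convex — as in lung tissue with its airways — methods
that assign molecules to the nearest nucleus or assume elliptic cells
misattribute large fractions of molecules, corrupting every downstream
single-cell analysis. `comseg` assigns molecules to cells from the RNA
coordinates and nucleus positions alone, without any cell-shape prior.

## The method

For each molecule at position $x$, a proximity-weighted expression
vector sums a linearly decaying kernel over its neighbours ($K = 40$
within $R_{pe} = D/2$):

$$V_g(x) = \sum_{y \in KNN(x),\ gene(y) = g} \frac{R_{pe} - \lVert x - y \rVert}{R_{pe}}$$

Pearson correlation of the stacked columns gives a gene–gene
co-expression matrix $W$, which weights a KNN graph over molecules
($K = 10$, edges no longer than $D/4$). Molecules inside one nucleus are
contracted into a "cell node", and the graph is partitioned by a
modified Louvain algorithm maximising

$$Q = \frac{1}{2m} \sum_{u,v}\left[w_{g_u g_v} - \frac{k_u k_v}{2m}\right]\delta(C_u, C_v)$$

over positively weighted edges, under the constraint that two cell nodes
never share a community. Community expression vectors
$V_C = \frac{1}{\#C}\sum_{x \in C} V(x)$ are clustered with Leiden into
transcriptomic profile labels; each nucleus centroid inherits a label
and claims the same-label molecules nearest to it in *geodesic* distance
(multi-source Dijkstra through same-label molecules only), up to a
maximum cell radius $R_{max}$. The output is a per-molecule cell id and
a cells × genes count matrix. Only $D$ (mean cell diameter, µm) and
$R_{max}$ need to be set per dataset.

The package also contains a synthetic tissue generator (regular grids,
interlocking L-shaped cells, nucleus-seeded irregular growth with
lacunar masks and nucleus dropout) and the benchmarking stack: per-cell
Jaccard index, wrongly-assigned (WA) and missing (MS) RNA fractions,
cosine cell-type calling, a nearest-nucleus Watershed baseline, and the
one-nucleus-per-cell ground-truth filter for membrane-derived
annotations.

## Worked example

Simulate a 4 × 4 grid of square cells with two cell types (five
exclusive markers each), segment it, and score against the known ground
truth:

```r
library(comseg)

b   <- simulate_benchmark("grid", nx = 4, ny = 4, seed = 7)
res <- comseg_segment(b$cloud, b$landmarks, b$config)
res
#> comseg_result
#>   cells: 16   molecules: 907 assigned / 8 unassigned
#>   communities: 23 (Q = 0.918), profile labels: 2
#>   mean molecules per non-empty cell: 56.7

jaccard_wa_ms(ground_truth(b$sim), res$assignment)
#> evaluation_report over 16 cells: J = 0.958, WA = 0.010, MS = 0.032

calls <- cell_type_call(res$profiles, b$model$profiles)
mean(calls$type == b$types[match(calls$cell_id, b$sim$cells$cell_id)])
#> [1] 1
```

915 molecules were placed; 907 end up in cells. The Louvain stage found
23 RNA communities at modularity 0.918, Leiden grouped them into exactly
the 2 planted expression profiles, and the per-cell Jaccard index of
0.958 with 1 % wrongly-assigned molecules means the recovered cells
almost coincide with the true ones — as they should on convex cells with
all nuclei present. Cosine cell-type calling against the model's type
centroids recovers every cell's planted type. On the L-shaped condition
(non-convex cells, 20 % of nuclei removed) the same pipeline roughly
halves the wrongly-assigned fraction of the nearest-nucleus baseline and
clearly exceeds its Jaccard index; run the acceptance script to see
those numbers computed live.

A command-line front end is provided:

```sh
Rscript inst/cli/comseg simulate --scenario lshape --nshapes 32 --dropout 0.2 --seed 1 --out sim/
Rscript inst/cli/comseg segment  --points sim/points.csv --nuclei sim/nucleus_mask.tiff \
        --voxel 0.15 --diameter 33.9 --rmax 52.5 --out seg/
Rscript inst/cli/comseg evaluate --pred seg/assignment.csv --truth sim/points.csv --out report.json
```

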