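---
title: "Models and methods behind osteoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osteoatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoatlas)
```

osteoatlas bundles three engines that are routinely needed when a
developmental single-cell atlas meets disease genetics and spatial data:
diffusion of GWAS signal over a gene-regulatory network (GRN) to rank
cluster-specific disease subnetworks, k-nearest-neighbour (KNN) transfer
of expression and labels from a droplet reference onto targeted in situ
sequencing (ISS) cells, and migration of raster histology annotations
onto a hexagonal spot grid with continuous distance-based axes. This
vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## Network propagation of GWAS and marker signal

### The diffusion model

The GRN is a typed tripartite graph: transcription factor (TF), region
(enhancer/peak, carrying a genomic interval) and gene nodes, with
non-negative edge importances on `tf-region`, `region-gene` and `tf-gene`
layers. Propagation treats the graph as **undirected**: regulatory
direction matters for interpretation, but signal placed on a gene should
implicate the regions and TFs regulating it just as signal on a region
implicates its targets, and undirected random walk with restart (RWR) is
the standard choice in network propagation. Edges duplicated across
directions are symmetrized by summing importance.

With column-stochastic transition matrix $T$ ($T_{ij} = w_{ij}/\deg_j$;
nodes with no incident weight get a uniform column so no probability mass
is lost) and a seed vector $s$ normalized to sum 1, the propagated score
is the fixed point of

$$ q = r\,s + (1 - r)\,T q, $$

found by power iteration. The restart probability defaults to
$r = 0.15$ — the PageRank damping convention; smaller $r$ diffuses
farther. Since $\lVert q \rVert_1 = 1$ at the fixed point, conservation
of seed mass is a testable invariant. The iteration stops when the L1
change drops below `tol` ($10^{-8}$ by default; the contraction factor is
$1-r$, so convergence is geometric) and errors, rather than returning
silently, if `max_iter` is hit.

### Seeds

*Trait seeds.* Per-SNP scores are $s = -\log_{10}(p)$ — the standard
GWAS signal scale; effect sizes are accepted in the input but unused by
default. Within a linkage-disequilibrium block the score is smoothed as
the $r^2$-normalized weighted mean
$s'_i = \sum_j r^2_{ij} s_j / \sum_j r^2_{ij}$ (the diagonal $r^2_{ii}=1$
keeps each variant's own score in the sum). This is a convex combination,
so smoothed scores stay inside the block's raw score range, and an
identity $r^2$ matrix leaves scores untouched. SNP positions are 1-based;
intervals are 0-based half-open (BED convention), so a SNP at position
$p$ overlaps $[\mathrm{start}, \mathrm{end})$ iff
$\mathrm{start} \le p - 1 < \mathrm{end}$. Gene (and TF) nodes collect
SNPs over their annotation padded by `window_bp` (default 10,000 bp — a
small symmetric pad; promoters and proximal enhancers are captured
without swallowing neighbouring loci); region nodes use their own
interval. The per-node seed is the **maximum** over collected SNP scores:
a sum would reward wide regions and long genes for their footprint rather
than their signal. Sum and mean remain available.

*Cluster seeds.* Marker scores per cluster are derived from differential
expression: counts are library-normalized to the median total, log1p
transformed, each gene is tested in-cluster versus rest with a two-sided
Wilcoxon rank-sum test (normal approximation with tie and continuity
correction — identical to `stats::wilcox.test(exact = FALSE)`, which the
test suite uses as an independent oracle), p-values are
Benjamini–Hochberg adjusted within the cluster, and the score is
$-\log_{10}(p_\mathrm{adj})$ where the in-cluster mean is higher, else 0,
capped at 300 to keep seeds finite at underflowing p-values. Any other
non-negative per-gene score can be substituted.

### Permutation null, combination, subnetworks

The propagation is repeated with `n_perm = 1000` uniform shuffles of the
seed values across **all** network nodes (zeros included) — the simplest
exchangeable null. A degree-matched shuffle would control for hubness but
requires binning choices; the all-node shuffle is the default and the
z-scores should be read accordingly (hubs are mildly favoured). Per node,
$z = (q - \mu_\mathrm{perm})/\sigma_\mathrm{perm}$, with $z := 0$ when
$\sigma_\mathrm{perm} = 0$ — a degenerate null (e.g. a constant seed)
must not produce $\pm\infty$ that would poison the later minimum.
Empirical p-values are $(1 + \#\{q_\mathrm{perm} \ge q\})/(1 + n_perm)$;
ties are counted with a relative tolerance of $10^{-12}$ because the
batched permutation propagation and the single observed propagation
round differently at the last bit. All permutations derive from one
`rng_seed`, making results bitwise reproducible.

Trait and cluster results on the same node universe combine by the
**per-node minimum of the z-scores**: a conservative intersection — high
combined score requires both disease signal and cluster specificity.
z-scores (not raw $q$) are the combination scale because they are
comparable across contexts. Nodes above `z_thresh = 2` are kept and the
connected components of the induced subgraph are returned ranked by mean
component score.

One open question in this design is whether trait and marker scores
should be propagated on one shared network or on lineage-subset networks
per cluster; both work here (the functions take whatever network they are
given), and one network per run is the default.

Node-wise empirical p-values share one set of permutations, so they are
positively correlated across nodes; the Kolmogorov–Smirnov uniformity
check used in the tests is therefore approximate, and its p-value
fluctuates more across simulation seeds than independent sampling would
suggest.

## Panel imputation and label transfer

Both modalities are restricted to the shared panel (sorted gene
intersection), then **separately per modality**: each cell is scaled so
its panel total equals the modality's median panel total, log1p
transformed, and each gene is z-scored within the modality. Per-modality
(not shared) medians are used because the two assays have incomparable
capture efficiencies. Genes with zero variance are set to 0 so they
contribute nothing to distances instead of propagating NaN. Euclidean
distance in this z-scored log space is the induced metric.

Neighbour search is **exact** (full pairwise distances): at the scales
this package targets, approximate indices buy nothing, and exactness
makes the brute-force oracle in the tests an equality, not a tolerance.
Ties break by reference cell order, so results are deterministic and
invariant to permuting the reference (up to genuine ties). `k = 15`
neighbours is the default. Unmeasured genes are imputed as the arithmetic
mean of the neighbours' **raw** counts — no re-normalization, so imputed
values are directly comparable to reference counts and always lie within
the neighbours' count range. Labels transfer by majority vote with
confidence = winning fraction; ties break by the smaller summed neighbour
distance, then lexicographically — every step deterministic.

## Hex-grid annotation and tissue axis

The spot grid uses 15 µm diameter and 15 µm centre spacing: rows along x
at the spacing, successive rows at pitch $15\sqrt{3}/2 \approx 12.99$ µm
with alternate rows offset by half the spacing, so the nearest-centre
distance is exactly the spacing and the spots tile with no gap. Image
coordinates follow the raster convention (origin top-left, x right, y
down) with the pixel at row $i$, column $j$ centred at
$((j-\tfrac12), (i-\tfrac12)) \cdot \mathrm{pixelsize}$ µm — stated
explicitly because nothing else pins it down.

Each spot takes the **median** pixel value in a disc of radius
(diameter/2)/4 (1.875 µm for 15 µm spots) around its centre, background
zeros included. "radius/4" is read literally as a quarter of the spot
radius — a small central disc that resists boundary bleed. The median
over integer labels uses the lower median on even counts so the result is
always a valid label, never an interpolated non-label. If the disc is
smaller than a pixel, the single nearest pixel is used (with a warning).

Distance features treat annotated pixel centres as the structure's point
set: level-0 structures use the mean distance to the ten nearest points
(all points if fewer than ten) — robust to ragged annotation boundaries;
level-1 structures use the single nearest-point distance. Which rule
applies to which structure is carried by the legend's level and can be
reassigned per structure. Annotations map to Visium spots by nearest grid
spot, with spots farther than `max_dist` (default 15 µm, one grid pitch)
left unannotated.

The axis between an origin and a target structure is
$d_o/(d_o + d_t) \in [0,1]$ on the level-1 nearest distances: bounded,
monotone along the perpendicular between two parallel structures,
parameter-free, rigid-motion invariant, and 0/1 exactly on the
structures' points. Spots at distance 0 from both structures get 0.5 with
a warning. The published axis's exact functional form is not specified
anywhere we could pin down, so this bounded form is the package's
documented default and is pluggable. Histology-driven manual bins are
consumed as an input table, never inferred.

## The synthetic study conditions

The generators exist so that every consumer is testable end to end with
no downloads; identical spec + seed gives bitwise-identical output, and a
single pipeline seed fans out to per-stage child seeds.

*GRN.* Tripartite preferential attachment (regions pick TFs, genes pick
regions, a minority of direct TF–gene links), made connected, with
importances in (0, 1]. The **planted module is a regulon**: a TF, its
regions, and each region's target genes, with cohesion edges tying every
module gene to at least two module regions and every module region to a
module TF. Early, less structured plantings (plain breadth-first node
sets) produced modules dominated by leaf regions that no realistic signal
could lift above the permutation null — a disease module that is not a
cohesive regulatory unit is not what the method is designed to find.
Defaults: 8 TFs, 40 regions, 80 genes, module of 20.

*GWAS.* Every gene/TF gets a 1 kb slot on a toy chromosome, 25 kb apart
so the default 10 kb gene windows never overlap neighbouring slots;
regions carry their slots in their ids. 300 background SNPs are uniform
in position and p-value; each planted node's interval receives 3 signal
SNPs with Beta(0.05, 1) p-values (heavily concentrated near 0 — a
stylized strong association with tunable shape). With the effect off, all
p-values are uniform, giving a null calibration fixture. SNPs are blocked
by position into LD blocks of 5 with constant within-block $r^2 = 0.6$.

*Expression.* Every gene belongs to exactly one cluster's program and is
up-regulated `fold_change`-fold (default 4) in that cluster, on
negative-binomial noise (mean 5, size 20 — deliberately modest
overdispersion, closer to aggregated/meta-cell counts than to sparse raw
droplets). This global cluster structure — rather than a handful of
markers in an otherwise exchangeable transcriptome — is what makes
held-out imputation meaningfully evaluable: a gene with no cluster
structure is unpredictable noise for *any* neighbour-based method, so
averaging per-gene imputation correlation over such genes would measure
nothing. The ISS dataset is an **independent draw** from the same cluster
parameters restricted to the panel (155 genes: each cluster's guaranteed
markers plus the most-expressed remainder), never a copy of reference
cells, so self-mapping cannot trivialize recovery. True ISS labels are
returned separately for evaluation only.

*Label image.* Named structures (bands, discs) rendered with integer
labels and levels; overlaps are rejected so ground truth is unambiguous.
The default scene is two parallel vertical bands ("suture", "bone"),
giving a strictly monotone axis fixture.

What the generators do **not** emulate: realistic LD from reference
panels, dropout and batch structure in counts, continuous differentiation
gradients (clusters are discrete), image noise or annotation error.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability under clean, planted conditions — not performance on real
atlases.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at deliberately desk
scale, chosen as the smallest sizes at which every property is
non-trivial: networks of 65–250 nodes (128 in the default pipeline
fixture), 1,000 permutations as the working convention, 250 reference and
250 ISS cells over 400 genes with a 155-gene panel, and label images up
to 100×100 px. Permutations are propagated as one batched power
iteration (all shuffled seeds as columns of one matrix), which is why a
full 1,000-permutation run over six contexts takes seconds at these
sizes. At atlas scale (10^5–10^6 nodes) the dense transition matrix would
need replacing with sparse operators; that is an engineering extension,
not a change of model.

## Known limitations

- The LD-weighting scheme and the per-node aggregation are defensible
  defaults, not canonical definitions; both are isolated behind
  configuration for exactly that reason.
- The all-node permutation null mildly favours high-degree nodes.
- Imputed counts are neighbour means: they shrink variance and cannot
  exceed the reference's dynamic range.
- The axis formula uses only two structures; multi-structure axes (e.g.
  through an intermediate osteogenic front) must be composed manually.
- Dense linear algebra bounds practical network size to a few thousand
  nodes.
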