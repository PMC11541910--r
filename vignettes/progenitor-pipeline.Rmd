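---
title: "Models and methods: droplet QC to differentiation programs"
author: "adipotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: droplet QC to differentiation programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adipotraj analyzes droplet single-cell RNA-seq of sorted PDGFRA+
adipocyte progenitors: which subpopulations exist, which genes mark them,
and in what temporal order progenitors proliferate and differentiate into
beige adipocytes after beta3-adrenergic stimulation. This vignette explains
each model in the pipeline, the parameters that matter, the numerical
choices, and what the bundled synthetic-data generator does and does not
emulate.

## The pipeline at a glance

```{r, eval = FALSE}
library(adipotraj)
sim <- simulateDropletData(simConfig(seed = 1))
res <- runPipeline(sim$sce,
                   immune_markers = my_hematopoietic_genes,
                   start_group_markers = my_progenitor_genes)
```

Stages, in order: barcode-rank knee filtering of empty droplets; cell-level
QC filtering; pooled size-factor normalization and `log2(x + 1)` transform;
highly-variable-gene (HVG) selection with a batch design matrix; k-means
immune pre-clustering and removal of immune clusters; HVG re-selection;
shared-nearest-neighbor (SNN) graph clustering on the first principal
components; two-stage marker identification; merging of clusters into
groups; and a per-condition trajectory analysis with early/middle/late
gene-program classification.

## Empty-droplet removal

Cell-containing droplets are separated from ambient-only droplets on the
barcode rank plot (log10 rank vs log10 total UMI). After isotonic
smoothing, the curve's upper knee is the point of maximum perpendicular
distance above the chord between the curve's endpoints; the lower
shoulder is found the same way on the sub-curve from the knee onward, below
its chord. The threshold is the geometric mean of the totals at the two
bends, which places it mid-cliff, strictly between the modal totals of the
two regimes. Barcodes with totals at or above the threshold are kept. The
two-pass construction matters: on realistic long-tailed ambient
distributions the global chord has no bend below it, so a single-pass rule
would return the top of the cliff and discard real cells. A distribution
without two regimes (e.g. all totals equal) raises an explicit error
suggesting a manual threshold.

## Cell-level quality control

Per barcode we compute the total UMI count, genes detected, the
mitochondrial UMI fraction and the fraction of genes not expressed; for an
all-zero barcode 0/0 is defined as 0. Cells are removed iff
`frac_mito > 0.10` or `frac_unexpressed > 0.995` — both strict, so a cell
sitting exactly on a threshold survives. The thresholds are the study's
fixed operating points and are exposed in the configuration
(`mito_max`, `unexpressed_max`). Multivariate outliers in the 2-D PCA of
standardized QC metrics are additionally *flagged* (robust Mahalanobis
distance beyond the chi-square(2) 0.99 quantile) but never auto-removed:
flagging replaces a visual inspection step, and removal should stay a
deliberate choice.

## Normalization

Per-cell size factors are estimated by deconvolution: cells are ordered on
a ring by library size, pools of consecutive cells (default sizes 21, 41,
61, 81, 101, capped at the cell count) are summed, each pool's median
gene-wise ratio to the average pseudo-cell gives one linear equation in the
member cells' factors, and the system is solved by least squares (with
low-weight single-cell equations for full rank). Cells with non-positive
solutions fall back to library-size factors with a warning; factors are
rescaled to mean 1. Counts are then divided by the factor and
`log2(x + 1)` transformed.

## Highly variable genes

Each gene's variance of log2 expression is computed on residuals after
removing batch means through a design matrix (a single batch reduces to an
intercept). A LOESS trend (span 0.3, degree 2, symmetric family) of log
variance against mean expression estimates the technical component; the
biological component is exactly total minus trend. Significance of excess
variance comes from a one-sided scaled chi-square test of the
variance ratio at the residual degrees of freedom, with BH adjustment; the
chi-square approximation is exact for Gaussian data on the trend and is
documented as an approximation for counts. HVGs are the genes with
`fdr <= 0.05` and biological variance strictly `> 0.1` (log2 scale, an
interpretation fixed here since the unit is not standardized in the
field).

## Clustering and groups

Cells are embedded with the first 50 principal components of the HVGs
(component signs fixed by making the largest-magnitude loading positive, so
results are machine-independent). Immune contaminants are removed first: a
k-means pre-clustering (k = 4, 10 restarts) is scored by mean expression of
a user-supplied hematopoietic marker set, and a cluster is dropped when its
score strictly exceeds the mean plus two standard deviations of the
*other* clusters' scores. The leave-one-out form matters at k = 4: a
single contaminated cluster inflates a pooled standard deviation enough to
mask itself. Final clustering builds a Jaccard-weighted SNN graph
(k = 20 neighbors) and optimizes modularity (Louvain) at a configurable
resolution; cluster ids are ordered by decreasing size.

Clusters are merged into groups (default 4: the non-adipogenic
AFEC niche, resting progenitors, proliferating and differentiating cells)
by hierarchically clustering (average linkage, correlation distance) the
cluster-mean profiles over the union of *initial* marker genes and cutting
the dendrogram. The initial markers — not the VIP-refined final ones — are
the right profile space: shared group-level genes carry the merge signal
and are exactly what the VIP stage removes from per-cluster final sets.

## Two-stage marker identification

**Stage 1 (screen).** Per cluster, a one-vs-rest Wilcoxon rank-sum test per
gene: exact enumeration of all rank assignments when both groups have at
most 8 cells (correct under ties), otherwise the normal approximation with
tie correction. The fold change is computed on the de-logged scale,
`(mean(2^x - 1) + 0.01) / (mean(2^x - 1) + 0.01)`, with the 0.01
pseudocount guarding empty denominators. Initial markers require
BH-adjusted p strictly below 0.05 and fold change strictly above 1.3.

**Stage 2 (VIP refinement).** For each cluster, a one-response PLS-DA
(NIPALS) of the one-vs-rest indicator is fitted on the column-standardized
expression of the union of all clusters' initial markers, with 2
components by default. Each gene's variable importance in projection is

$$VIP_j = \sqrt{p \cdot \frac{\sum_a SS_a\, (w_{ja}/\lVert w_a\rVert)^2}
{\sum_a SS_a}},$$

where $p$ is the gene count, $w_a$ the X-weights and $SS_a$ the response
variance explained by component $a$; by construction
$\sum_j VIP_j^2 = p$. Fitting on the union is essential: VIP measures
*relative* contribution, so a model shown only one cluster's own
(uniformly discriminative) markers returns VIPs near 1 for every gene and
can never rank them. The null distribution is estimated empirically by
refitting under 1000 random permutations of the labels over cells
(vectorized across permutations via a deflation-free PLS1 recursion),
pooling the permuted VIPs of all genes, and placing a Gaussian kernel
density with Silverman's bandwidth over the pool; each observed VIP's
p-value is the closed-form upper-tail mass of that Gaussian mixture, so it
is strictly inside (0, 1). This null-calibrated p *is* the adjusted
quantity gated at 0.05 for the final-marker call; a BH-adjusted column is
also reported and can be used instead (`vip_adjust = "BH"`), but note that
the $\sum VIP^2 = p$ mass constraint caps how many genes can clear a BH
threshold simultaneously, which makes that variant very conservative.
Permutations are global over cells; a within-batch variant would be a
straightforward extension but is not implemented.

## Trajectories and gene programs

Trajectory features are re-derived within the progenitor, proliferating
and differentiating cells: HVG selection, graph clustering and the marker
pipeline are re-run on those cells and the union of final markers across
the sub-clusters is the feature set (if a single cluster is found, the HVG
set is used — a one-vs-rest contrast is undefined).

The principal tree is deliberately simple and transparent: k-means
centroids (default 20) in the feature PCA space (default 2 dimensions),
connected by a Euclidean minimum spanning tree; leaf branches attracting
fewer than 5% of the projected cells are pruned iteratively, smallest
first, so noise spurs do not masquerade as bifurcations. Cells are
projected orthogonally onto the nearest tree edge. The root is either a
node index or a marker gene set (the leaf whose nearby cells score highest
becomes the root; the default start state is the resting-progenitor
group). Pseudotime is the arc-length geodesic distance from the root to
each cell's projection, rescaled to [0, 1]; branch ids label the subtrees
past the branch point closest to the root (0 marks the trunk). An
externally computed pseudotime (e.g. from a DDRTree implementation) can be
substituted wherever a Trajectory's ordering is consumed, since smoothing
and classification only need an ordered cell vector.

Expression along a path (trunk plus one branch) is smoothed by a centered
rolling mean over the pseudotime-ordered cells — window 150 for the
control condition and 300 for the treated one, the study's operating
points — with truncated windows at the edges so the profile keeps one
position per cell. Genes are z-scored, Ward-clustered (Euclidean distance)
into 3 clusters per path, and each cluster is labeled from the shape of
its min-max-normalized mean profile: a transient program — one that falls
back below 2/3 of its maximum before the end of the path — is *middle*,
and a sustained program is *early* or *late* according to whether it first
reaches 2/3 of its maximum before pseudotime 1/3 or after 2/3. Shape and
onset, rather than peak position, are deliberate: an early program that
saturates holds its maximum anywhere on the plateau and rolling smoothing
shifts apparent peaks, while activation time and persistence are stable
under both. `comparePaths()` reports per-label
Jaccard overlaps between the two branches of a bifurcating trajectory.

## Enrichment

Gene-set enrichment uses the EASE score: the one-tailed hypergeometric
upper tail with the overlap penalized by one,
$p = P[X \ge k - 1]$, $X \sim \mathrm{Hypergeom}(N, K, n)$, so overlaps of
0 or 1 are never significant and the penalty is conservative relative to
the plain Fisher tail. The universe defaults to the genes surviving QC and
expressed in at least one retained cell; no multiple-testing correction is
applied by default (significance is plain `p < 0.05`), with BH available
behind a flag. Gene sets come from user-supplied GMT files; no annotation
service is queried.

## The synthetic-data generator

`simulateDropletData()` plants ground truth for every stage: empty
droplets drawn multinomially from the ambient profile (the mean of
true-cell expectations) with Poisson totals at `ambient_scale` (default
0.01) of a true cell's depth; low-quality cells (5%) with mitochondrial
share drawn uniformly from [0.2, 0.6]; an immune contaminant population
(8%) with its own 20-gene marker block; four groups over nine clusters
with 10 cluster-specific and 10 group-shared planted markers each (log2
effects 1.5 and 2); negative binomial counts (dispersion 0.1) with
lognormal size factors (log-sd 0.25) and per-batch multiplicative gene
factors (log-sd 0.1, two batches); and per-condition trajectories —
linear in the control arm, bifurcating at pseudotime 0.65 in the treated
arm — carrying 20-gene early, middle and late programs (normalized
logistic and Gaussian-bump curves, amplitude 3) plus a branch-specific
sustained-proliferation program (amplitude 6) on the non-differentiating
arm.

Two generator choices deserve emphasis. Planted marker and program genes
draw their baseline abundance from a moderately expressed range
(`rlnorm(meanlog = 1, sdlog = 0.5)` relative abundance), the way real
markers are reliably detected genes; markers planted on sub-count genes
are invisible to any method and test nothing. And trajectory-group
clusters are consecutive pseudotime *stages* whose markers ramp
triangularly around the stage center (group markers plateau with a sharp
0.02-wide ramp): maturation is a continuum, and discretely switching
marker blocks would make all stages near-equidistant in expression space —
a geometry in which no tree-based method, this one included, can order
cells.

What the generator does **not** emulate: ambient contamination inside true
cells, doublets, UMI saturation, gene-length or GC biases, condition
compositional shifts beyond topology, or dropout beyond what the negative
binomial implies. Tests passing on these simulations therefore demonstrate
the pipeline's correctness under its own model assumptions, not robustness
to every artifact of real droplet data.

## Problem sizes and determinism

The packaged analyses and tests run at desk scale, chosen so the full
structure (two conditions, two batches, nine clusters, both topologies) is
present: 3000 true cells and 10000 empty droplets over 2000 genes by
default; 1500 cells for marker recovery; 500 cells for size-factor and
HVG calibration; 200 permutations over 3 replicate datasets for the VIP
null calibration. Every stochastic stage takes an explicit seed, restores
the caller's RNG state, and the pipeline manifest records an md5 hash of
every stage output; re-running with identical inputs, configuration and
seed reproduces identical manifests.

## Known limitations

The principal tree is a deliberate simplification of graph-regularized
embedding methods; it assumes the trajectory is low-dimensional in the
feature PCA space and will fold on data whose maturation signal is
strongly discretized. The variance-ratio HVG test is approximate for
counts. The VIP permutation null pools across genes; genes with unusual
marginal distributions inherit the pooled null. The EASE universe choice
is configurable but defaults to expressed genes, which can differ from
annotation-service backgrounds. Cluster counts are data outcomes: the
pipeline does not try to force nine clusters, only to recover the planted
group structure.
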