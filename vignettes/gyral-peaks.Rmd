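---
title: "Methods: cross-species gyral peak analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species gyral peak analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind each
stage, the parameters that matter and their defaults, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the procedure left room.

## The landmark and its detection

Gyral peaks are the local height maxima of gyri. Height is carried by the
`sulc` metric — the signed displacement of each vertex from a hypothetical
mid-surface, averaging zero over the hemisphere — under the convention that
*lower* sulc means higher on the gyrus. A vertex `v` is a peak of a subject
iff

* `sulc[v]` is strictly lower than `sulc[u]` for every `u` in the k-ring of
  `v` (all vertices within k mesh edges), and
* `sulc[v]` lies below the `gyral_quantile` quantile of the hemisphere's
  sulc distribution.

`k` defaults to 4 on human-resolution templates (~32k vertices per
hemisphere) and 3 on macaque templates (~20k), matching the ring sizes used
for these mesh densities in the gyral-peak literature. The gyral restriction
implements "peaks are defined within the gyri"; no threshold is published,
so the default is the weakest defensible one — the median split
(`gyral_quantile = 0.5`), exposed as a parameter. Ties: a vertex that merely
*ties* its ring minimum is not a peak. Landmark detection should not invent
an arbitrary winner between two equal candidates, so tied minima yield no
peak. A candidate whose ring contains missing sulc values is skipped with a
warning rather than silently compared against an incomplete ring.

Strictness buys a useful invariant (tested): two peaks can never lie within
k edges of each other, and growing k can only remove peaks.

## Group clustering of the count map

Subject peaks live on a common template (vertex-to-vertex correspondence
across subjects is assumed, as produced by any surface registration), so
they accumulate into a per-vertex **count map**. Two steps turn counts into
group-wise clusters.

**Anisotropic smoothing.** Each iteration replaces a vertex value by a
similarity-weighted average over its ring neighborhood plus itself, with
weights `exp(-(x_u - x_v)^2 / (2*beta^2))` (a Perona–Malik-style operator).
Similar values pool; sharp steps act as edges and are preserved — exactly
what a watershed needs, since it consumes the extrema. The update is a
convex combination, so the field stays non-negative and its maximum never
grows (both tested). Defaults: `iterations = 3`, `ring = 1`, `beta = 2`
count units — steps of more than about two subjects' worth of counts are
treated as structure, not noise. `iterations = 0` is the exact identity.

**Watershed.** Vertices with smoothed value above `flood_floor` are visited
in strictly decreasing order (ties by ascending vertex index — every
tie-break in the package is by index, for reproducibility). A vertex without
labeled neighbors founds a basin; otherwise it joins the basin of its
highest-valued labeled neighbor. Where a vertex touches several basins it is
a saddle: the lower-peaked basin of each pair merges into the other iff its
relative prominence `(peak - saddle) / peak` is below `saddle_ratio`
(default 0.15). Basins whose raw-count mass falls below `min_mass` are
discarded; the surviving basin's center is its smoothed-count argmax. The
function-level defaults (`flood_floor = 0`, `min_mass = 2`) are permissive;
the *pipeline* defaults are scaled to the cohort:

* `flood_floor = 0.025 * n_subjects` — a basin must be seeded where at
  least ~2.5% of subjects' peak mass concentrates after smoothing, so an
  isolated single-subject peak cannot found a cluster;
* `min_mass = 0.5 * n_subjects` — a group-wise cluster is a
  majority-consensus landmark.

These scalings follow from the arithmetic of the count map rather than from
any particular run: a planted locus expressed in most subjects carries mass
close to `n_subjects`, while chance co-occurrences of per-subject noise
peaks must collide within a one-ring-scale basin to pool mass, which caps
their mass far below half the cohort. At the default design (20 subjects)
the two populations are separated by roughly a factor of three in mass.

## Shared and unique clusters

One species' clusters are pushed through a total vertex correspondence map
(the output of a cross-species registration, which this package consumes,
not computes) onto the other's template. A candidate pair is **shared** iff
its Dice overlap `2|A∩B|/(|A|+|B|)` is positive *or* the geodesic distance
between centers is below `d_max = 7` mm. Geodesics are shortest paths on the
edge graph with Euclidean edge lengths (Dijkstra) — the standard
surface-tooling approximation; whether the original criterion used exact
polyhedral geodesics is unknowable from the text, and at 7 mm the two agree
within mesh resolution.

Pairing is **one-to-one greedy**: candidates sorted by descending Dice, ties
by ascending center distance, then by cluster ids, accepted while both sides
are free. "Pairs" requires injectivity and greedy-by-overlap is
deterministic and oracle-checkable (the tests compare it against exhaustive
search over all one-to-one matchings maximizing matched count then total
Dice). Unmatched clusters are the species-unique set, so shared ∪ unique
always partitions each species' clusters (tested). Cluster *center* is the
smoothed-count argmax — the cluster's consensus peak — since no definition
of center is published.

**Consistency** of a cluster is its raw-count mass divided by `n_subjects`:
mean peaks per subject captured by the cluster. Shared-pair consistencies
feed an OLS regression of one species on the other, reported with Pearson r,
R², and the two-sided slope p-value; a constant response is flagged as
degenerate rather than fit silently.

## Class comparisons

Subject peaks inherit a class from the group clusters containing them
(peaks in neither class stay unclassed). The unit of analysis everywhere is
**one value per subject per class** — subject-level means — not peak-level
pooling, which would pseudo-replicate. Anatomical features are compared with
the pooled two-sample t-test, two-sided; Welch's unequal-variance t is used
for gene expression, where the two region classes differ in size and spread.
Each comparison family (features; connectome metrics; atlases) is
FDR-corrected by Benjamini–Hochberg within the run. Sulc is compared on its
absolute value, since peak height is reported as a positive depth magnitude.
Local surface area at a vertex is the mean area of its incident triangles
divided by the whole-mesh mean of that quantity (global mean exactly 1,
tested to 1e-9).

## Connectome metrics

The template is parcellated into approximately equal, contiguous patches by
farthest-point seeding plus nearest-seed geodesic assignment (deterministic
given a seed). Functional connectivity is the Pearson correlation of mean
patch time series, Fisher z-transformed with correlations clipped to
±(1 − 1e-7); structural connectivity counts streamline endpoint pairs per
patch pair. Subject matrices are averaged element-wise, then per ROW the top
`fraction = 0.10` of connections is kept (ceiling of `fraction*(n-1)` per
row, ties by column index) and the matrix symmetrized by element-wise
maximum — the union of row-wise survivors, declared explicitly because
row-wise thresholding alone breaks symmetry. Keeping the *largest* values
means strongly negative Fisher-z edges are zeroed by construction.

Nodal metrics follow the weighted conventions of the standard connectome
toolkits: binarized degree; strength as weighted row sum; Onnela clustering
coefficient with weights rescaled by the maximum; betweenness and efficiency
on edge lengths `1/weight`, betweenness unnormalized over unordered pairs
with endpoints excluded, unreachable pairs contributing zero efficiency. The
toolkit conventions are not spelled out in print, so the tests pin them
against a brute-force oracle (Floyd–Warshall plus exhaustive shortest-path
enumeration) on small graphs.

## Gene selection

Regions of a gene-expression parcellation are labeled shared / unique /
other by the cluster centers they contain (shared takes precedence in mixed
regions; "other" is excluded from fitting). With shared = 1, unique = 0 and
standardized gene columns, the lasso objective is

```
(1/(2n)) * sum_i (y_i - w0 - w'x_i)^2 + lambda * ||w||_1
```

with an unpenalized intercept, solved by cyclic coordinate descent with
exact soft-threshold updates to a 1e-7 coefficient-change tolerance (a
compiled kernel; verified against an independent implementation of the same
objective in the test suite). The per-sample-normalized scale is the one on
which the published 10⁻⁴…1 λ grid is meaningful: on the unnormalized
residual-sum scale, λ_max for a standardized design of ~100 regions is far
above 1 and no grid value could ever null the model. Penalized *linear*
regression with a 0.5 threshold for accuracy — not logistic lasso — is used
because the printed cost is squared-error and both accuracy and MSE are
reported.

λ is chosen by stratified 10-fold cross-validation over 25 log-spaced grid
points: maximize pooled CV accuracy, break ties by minimal CV MSE, remaining
ties by the larger (sparser) λ. Fold paths are warm-started from large to
small λ; path fits cap at 300 sweeps because the `p > n` interpolation tail
of the grid converges slowly and never wins selection, while the final model
at the chosen λ is always fit to full tolerance. A stratified 25% holdout is
split off before CV and only used to report test accuracy/MSE; the published
workflow reports separate train and test accuracies without stating the
split, so the proportion is a package default, not a reproduction.

Welch's t with BH-FDR over the *selected* set flags differentially expressed
genes at corrected p < 0.05. A caveat documented deliberately: testing genes
*selected on the same data* is anti-conservative (post-selection inference),
and under a global null the accuracy-first CV tie-break often picks a model
whose selected genes are exactly the most class-correlated noise genes; the
FDR correction over the small selected family does not undo that selection
bias. The test suite measures this calibration behavior directly; results on
real data should treat the per-gene significance flags as descriptive
follow-ups to the selection, not as inference protected at the nominal
level.

## The synthetic study design

`synthetic_design()` declares every input with known ground truth:

* **Templates**: icospheres (human-like: subdivision 5, radius 80 mm,
  ~10.2k vertices, 2.6 mm edges; macaque-like: subdivision 4, radius 35 mm,
  ~2.6k vertices, 2.3 mm edges). Peaks are defined on the sulc *field*, so
  the carrier geometry can stay simple; small radial expansions (+10%) at
  shared loci and contractions (−5%) at unique loci drive the local
  surface-area contrast through real geometry rather than a painted map.
* **Loci**: 6 shared + 4 unique per species on dodecahedron-vertex
  directions, pairwise ≥ 41.8° apart, so unique loci sit ≥ 3×7 mm from
  every opposite-species locus image and shared loci pair across species by
  construction. The correspondence map is the nearest-vertex map after
  undoing a known rigid rotation (8° about z) and radial rescale; paired
  shared loci map within 7 mm (tested).
* **Subject sulc**: each locus a subject expresses contributes a wide gyral
  depression plus a sharp crown (Gaussians in great-circle distance,
  depths 1.2 shared / 1.0 unique, width 6 mm human / 4 mm macaque), centered
  within `jitter_rings = 1` edges of the template locus; plus a smooth
  noise field (iid Gaussian averaged twice over the 1-ring, rescaled to
  `noise_sd = 0.1` — 10% of the unique bump depth). Smooth noise models the
  spatially correlated residual variation of registered surface maps; it
  still produces scores of spurious per-subject peaks, which is realistic —
  individual peak maps are dense — and is exactly what the count-map mass
  filter exists to reject.
* **Presence**: a locus is expressed in a subject with probability 0.95
  (shared) / 0.80 (unique): folding landmarks are not universal, and
  species-shared ones are the more consistent class. This plants the
  consistency direction and gives cluster masses binomial spread.
* **Features**: curvature lower, thickness lower, myelin higher at shared
  loci (narrow Gaussian contrasts plus smooth noise), matching the reported
  anatomical directions; thickness and myelin exist only for the human-like
  species, as in the source datasets.
* **Connectivity**: patch time series are community-structured
  (12 communities, within-community correlation 0.7, 600 timepoints);
  patches containing shared loci instead carry an equal mixture of all
  community signals, so after top-10% thresholding they emerge as hubs —
  communities are smaller than the per-row retention budget, so every
  member's row reaches for the hubs and max-symmetrization gives hubs high
  degree and strength. Structural endpoints are drawn mostly within
  communities with a boosted rate through hub patches.
* **Atlases**: farthest-point parcellations at 24/60/120 regions whose seed
  layout is pinned to the planted truth — two flanking seeds per shared
  locus (a region boundary bisects it) and the unique centers as their own
  seeds (region interiors) — planting the higher 3-ring region diversity of
  shared peaks. A 12-region atlas carries the standard lower/higher-order
  network names for the tally stage.
* **Genes**: 55 shared / 65 unique / 30 other regions × 200 genes, N(0,1)
  background, 5 informative genes shifted ±d/2 by class with `effect_d = 2`.

Every generator is a pure function of the design (which carries the seed);
two runs with equal designs are byte-identical.

**What passing tests do and do not show.** The generator emulates the
*statistical structure* the analysis assumes — consistent minima with
jitter, smooth inter-subject noise, class-contrasted features, hub
structure, boundary-seeking shared loci, sparse informative genes. It does
not emulate folded cortical geometry, registration error beyond nearest-
vertex rounding, distance-dependent connectivity, spatially autocorrelated
gene expression, or hemispheric asymmetries. Recovery on this design
validates the machinery and its wiring, not the empirical claims about real
human and macaque cortex, which require the original imaging datasets.

At desk scale one mismatch is structural: ten synthetic clusters can label
only about ten atlas regions, while the gene lasso needs on the order of a
hundred classed regions (the real study had 192 clusters over a 500-region
atlas). The pipeline therefore records the spatial region classes from
`label_regions()` but fits the lasso on the design's region-class table,
which emulates the real cardinalities.

## Sizes, determinism, degenerate inputs

The default design runs the full pipeline in well under a minute on one
CPU; the test suite, including the oracle sweeps (100 random peak maps, 50
watershed maps, 200 matching instances, 100 small graphs, 40 + 20 gene
seeds), completes in a few minutes. Files store 0-based vertex indices (the
convention of the surface-file ecosystem); the R API is 1-based, converted
at the I/O boundary. Degenerate cases are explicit throughout: Dice of two
empty sets is an error, not 0; an unreachable vertex pair is an error, not
infinity; zero-variance t-tests return a flagged degenerate result; a
constant regression response is flagged; an all-zero count map clusters to
an empty set; constant patch time series get missing connectivity rows with
a warning.
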