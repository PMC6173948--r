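---
title: "Unsupervised fuzzy clustering of time-course data: methods and design choices"
author: "fcmvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised fuzzy clustering of time-course data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmvalid)
```

## The problem

Model-free analyses of fMRI ask which voxels share a temporal behaviour
without assuming a response model. Fuzzy c-means (FCM) is a standard tool for
this: it groups the n voxel time-courses (rows of an n x p matrix X) into c
clusters, each represented by a prototype time-course V_j, while letting each
voxel belong to every cluster with a degree of membership U_ij in [0, 1]
(rows of U sum to 1). The catch is that c must be supplied, and in real data
the "true" number of clusters is unknown. The standard remedy is an
unsupervised sweep: fit every c in a candidate range, score each fitted
partition with a cluster validity (CV) index that trades off compactness
(tight clusters) against separation (distinct clusters), and select the c
that optimises the index. This package implements the full pipeline — the
clustering, the measures, eight CV indices, the sweep, a synthetic benchmark
generator with ground truth, and morphological granulometry of crisp 3D
cluster maps — so that the behaviour of every ingredient can be inspected,
not just the final selection.

## The clustering model

FCM minimises

$$J_m = \sum_{i=1}^{n}\sum_{j=1}^{c} U_{ij}^m \, D_{ij}^2,$$

alternating the membership update
$U_{ij} = 1 / \sum_k (D_{ij}/D_{ik})^{2/(m-1)}$ with the centroid update
$V_j = \sum_i U_{ij}^m X_i / \sum_i U_{ij}^m$. The degree of fuzziness
m > 1 controls how soft the memberships are: near 1 the assignment is
crisp, and as m grows every membership flattens toward 1/c.

Similarity is temporal, not geometric, so D is built from the Pearson
correlation CC_ij between a voxel and a centroid. Two transforms are
provided:

* `hyperbolicDistance()`: D = (1 − CC) / (1 + CC);
* `modifiedDistance()` (the default): D = (√|CC| − CC) / (√|CC| + CC).

Because √x ≥ x on [0, 1], the square-root form separates mid-to-high
correlations by larger *ratios* than the plain hyperbolic form — and ratios
of distances are exactly what the membership update consumes. The package's
property tests verify this ratio inequality on a 0.4–0.95 correlation grid.

Numerical conventions, chosen once:

* CC is clamped to [−1 + 10⁻⁶, 1] before either transform, so the pole at
  CC = −1 yields a large finite distance; the membership update divides by
  distances and must never receive infinities.
* The 0/0 form of the modified transform at CC = 0 is defined by continuity
  as 1 (both one-sided limits equal 1).
* A constant (zero-variance) time-course has no defined correlation; it is
  assigned CC = 0 — the maximal finite distance — with a warning, since a
  flat voxel carries no temporal signal.
* A voxel at zero distance from one or more centroids receives membership 1
  split equally across the coincident centroids (the standard FCM
  singularity convention).
* All reductions over clusters run in fixed index order, so runs are
  bit-reproducible given the seed.

Initialisation draws each membership row uniformly on the simplex
(normalised uniform variates) from a seed; `multiInitFCM()` re-runs the fit
from `nInit` consecutive seeds and keeps the minimum-J_m solution, the usual
guard against local minima. Convergence stops when the largest absolute
membership change falls below `tol` (default 10⁻⁵) or after `maxIter`
(default 300) iterations; a `stopRule = "deltaJ"` option stops on objective
improvement instead, the convention of classic FCM implementations. Both the
tolerance and the cap are exposed rather than hard-coded.

One caveat documented by the tests: the centroid update above is the exact
minimiser of J_m only for the Euclidean metric. With a correlation-based D
it is a heuristic, so the objective is not mathematically guaranteed to
descend at every step. In practice descent holds to rounding error on
low-noise data (asserted at 10⁻⁶ relative per step in the tests), while on
very noisy data occasional per-step increases of order 10⁻⁵ relative can
occur before the run settles.

## Compactness and separation measures

All building blocks are evaluated on a converged partition by
`computeMeasures()` and stored in a `MeasureSet`: fuzzy cardinalities
n_{m,j} = Σ_i U_ij^m and variations σ_{m,j} = Σ_i U_ij^m D_ij²; the
compactness scalars π_{m,1}, π_{m,m} and FC; the separation scalars K_m,
K_1, FS, S, SS and the fuzzy overlap FO = FS/FC; the between-centroid
distances Vdmin, Vdmax and per-cluster minima; the dissimilarity
coefficients ID_intra and ID_inter; and the objectives J_1 and J_m. Closed
forms anchor the tests: a maximally fuzzy partition has FC = 1/c and
FS = (c − 1)/2 exactly, and every measure is checked against a naive
double-loop implementation to 10⁻¹² on random fixtures.

Two conventions here were genuinely open and deserve an explanation:

**Norm.** The centroid-space norms in K_m, K_1, S, SS and the Vd measures
are Euclidean in the p-dimensional time-course space, even though the
clustering metric is correlation-based. That is the convention under which
these separation measures were originally defined, and it is the one that
reproduces the recovery benchmark below; a `norm = "correlation"` switch
substitutes the modified correlation distance for users who want metric
consistency (in our experiments it degrades high-noise recovery).

**Reference point.** K_m, K_1 and S measure how far centroids sit from "the
data". The package references them to the scalar grand mean of X (the mean
over all voxels and time points, broadcast over time), not to the mean
time-course vector. The distinction only matters on degenerate data, but
there it is decisive: on data with no structure, every centroid converges
onto the mean time-course itself, so a vector reference leaves K_m and S at
the level of the convergence residual — numerical noise with no meaning —
whereas the grand-mean reference keeps them on the scale of the signal. The
result is the expected textbook behaviour on a structureless single-cluster
dataset: S independent of c, K_m tracking c^(1−m), and the product
π_{m,1}·K_m constant across c (the acceptance suite checks the product to a
10% coefficient of variation; measured, it is constant to ~10⁻¹⁰). The
vector convention remains available as `reference = "meanTimecourse"`.

## The eight validity indices

`computeIndexPanel()` evaluates, per candidate c:

| index   | definition                                     | optimum |
|---------|------------------------------------------------|---------|
| cv_rlr  | Σσ_{1,j}/(c·‖σ_X‖) + (1/α)(Vdmax·SS/Vdmin)     | min     |
| cv_zle  | α·(S/π_{m,1}) − FS/FC                          | max     |
| cv_gv   | K_1/(c²·J_1)                                   | max     |
| cv_kp   | π_{1,1}/c + (1/α)(c/Vdmin)                     | min     |
| cv_pbm  | (α/c)·(Vdmax/J_m), α = n                       | max     |
| cv_wy   | Σ_j [n_{1,j}/max(n_{1,j}) − exp(−Vd²_{min,j}/S)] | max   |
| cv_bws  | K_m/π_{m,m}                                    | max     |
| cv_new  | K_m·(ID_inter/ID_intra)·(FC/J_1)               | max     |

The α constants of cv_rlr, cv_zle and cv_kp are normalisations fixed from
the partition at the top of the sweep (c = cMax): α_rlr = (Vdmax/Vdmin)·SS
there, α_zle = FO there, and — by analogy, since no published convention
exists for the Kim-Park case — α_kp = c/Vdmin there. Each makes the
corresponding term equal 1 at cMax, putting the two halves of the index on
a common scale. The sweep therefore always fits cMax before finalising any
index. cv_new multiplies the separation K_m, the dissimilarity ratio
ID_inter/ID_intra and the compactness-per-fit FC/J_1; these are precisely
the measures that behave differently on single-cluster and structureless
data, which is what makes the index robust on noisy data with many
clusters.

**Redundancy sentinel.** When the requested c exceeds the structure the
data supports, surplus centroids collapse onto existing ones; the smallest
between-centroid distance then equals the convergence residual and any
index that uses Vdmin becomes numerical noise. Such a partition is the
(c−1)-partition in disguise, not a genuine c-cluster solution, so the whole
index panel is flagged degenerate (`NA`) whenever
Vdmin < 10⁻³ · sqrt(Σ_t var_t(X)), and degenerate values can never win the
selection (`selectCOpt()` excludes them; ties break toward the smaller c,
favouring parsimony). The 10⁻³ factor sits several orders of magnitude
above observed merge residuals and several below genuine centroid
separations at both benchmark noise levels. On fully degenerate data every
panel entry is `NA` and the sweep reports no selection for the affected
index — itself the correct diagnosis that the data cannot be clustered
further.

## The synthetic benchmark

`generateSuite()` builds the 22-dataset benchmark the package is validated
against, with n = 1000 voxels and p = 100 time points throughout:

1. a single-cluster "null" dataset: one standard-normal prototype
   replicated n times plus unit-variance Gaussian noise;
2. a structureless dataset of n i.i.d. standard-normal time-courses;
3. ten datasets with the true cluster count c_true = 2..11 at noise
   σ = 1;
4. the same ten counts at σ = 4.

Each clustered dataset replicates c_true prototype time-courses r_j times
(equal split, remainder to the first clusters; a `sizes` argument allows
imbalance experiments) and adds i.i.d. N(0, σ²) noise. Prototypes are drawn
i.i.d. standard normal and rejection-sampled row by row until every pairwise
|correlation| is below 0.1: each new prototype is redrawn against the
accepted ones (budget 10,000 draws per row). Whole-set rejection would be
astronomically wasteful here — with p = 100 the pairwise correlation of
independent rows has standard deviation ≈ 0.1, so 55 simultaneous
constraints are essentially never met in one joint draw, while the per-row
scheme produces the identical admissible distribution cheaply. All
randomness derives from one base seed via per-member derived seeds, so the
suite is reproducible as a unit and per member.

At σ = 1 a voxel correlates ≈ 0.7 with its prototype and recovery is easy;
at σ = 4 the correlation drops to ≈ 0.24 and the benchmark probes
robustness. What the generator deliberately does *not* emulate: spatial
autocorrelation of fMRI noise (smoothing-induced voxel dependence),
physiological and motion artefacts, low-frequency drifts, and the
ill-balanced situation where task-related voxels are a tiny fraction of the
brain. Passing the benchmark therefore shows correctness of the machinery
and noise robustness under i.i.d. Gaussian conditions, not performance on
real fMRI.

## What the benchmark shows — and a documented reproducibility limit

With m = 1.5, ten restarts, and c swept over 2..19 (the acceptance suite's
conditions), all eight indices select c_true on the σ = 1 datasets with
c_true ∈ {3, 7, 11}, across seeds. At σ = 4 the picture the tests enforce is
partial: cv_new and cv_bws still recover c_true = 3 (with at least one
other index failing), and cv_new recovers c_true = 7 on most seeds, but at
c_true = 11 cv_new's argmax typically lands above 11 in this
implementation.

The mechanism is worth recording. Beyond c_true, two families of fixed
points exist: *twin collapse* (surplus centroids duplicate existing ones;
J_m stalls) and *noise carving* (surplus centroids split a cluster's noise
cloud along its strongest random direction; J_m genuinely decreases).
Seeding the high-noise benchmark at c = 18 with the true 11-cluster
structure plus duplicated centroids is stable but yields a higher final
objective than random multi-restart optimisation, which escapes into
carving solutions. A minimum-J_m-of-restarts rule — the selection this
package implements — therefore systematically returns carving solutions at
high noise, whose K_m keeps growing with c; an optimiser that lingers in
twin-collapse minima would instead show K_m peaking at c_true and stronger
index behaviour there. In other words, the high-noise/high-c selection
behaviour of index panels is a property of the optimiser's basin of
attraction, not of the index formulas alone. Users comparing against other
FCM implementations should expect exactly this kind of divergence; the
redundancy sentinel above reports the twin-collapse case honestly when it
does occur.

The fuzziness scan (`mSensitivityScan()`) reproduces the expected
qualitative fingerprints: cv_new recovers c_true at σ = 1 for m anywhere in
1.2–2.5, while at σ = 4 with many clusters it underestimates once m ≥ 2 —
soft memberships flatten toward 1/c, centroid contrasts wash out, and
compactness terms dominate. This is why m = 1.5 is the package default.

## Granulometry of crisp cluster maps

For spatial reporting, `crispPartition()` binarises memberships: a voxel is
labelled argmax_j U_ij only when its largest membership strictly exceeds
the threshold (default 0.5; thresholds below 0.5 are rejected because row
sums of 1 then no longer guarantee a unique label). `regionSizes()` then
computes connected components within each label under 6-, 18- or
26-connectivity (default 26: face, edge and corner adjacency) and reports
every region's size plus single-voxel counts — small isolated regions being
the typical signature of noise-driven clusters. The compiled labelling is
verified against a breadth-first flood-fill oracle on random volumes, and
region counts are monotone in the connectivity (26 ≤ 18 ≤ 6). Grid
coordinates are array indices; physical units enter only through the voxel
volume in the report.

`readNiftiTimecourses()` flattens a 4D NIfTI volume (with an optional 3D
mask) into the voxel-by-time matrix the rest of the package consumes, and
`writeLabelVolume()` writes label maps back out. `correlateWithDesign()`
screens centroids against an experimental regressor (e.g., a block-design
boxcar) and flags clusters with |r| ≥ 0.5 at p < 0.001 as task-related —
the default screen for "which cluster is the activation".

## Problem sizes used by the test suite

Unit tests run on small fixtures (tens to hundreds of voxels) chosen to be
in the regime they probe: the single-cluster degeneracy, for instance, only
manifests once n is comfortably larger than p (n = 300, p = 40 in the
tests; at n ≈ p random noise has enough eigenvalue spread that FCM finds
genuine splits even in structureless data, which is correct behaviour, not
a bug). The acceptance-level checks run at the full benchmark scale —
n = 1000, p = 100, c = 2..19, ten restarts, ten seeds per condition — which
the compiled core completes in a few seconds per sweep.

## Known limitations

* Descent of J_m is heuristic under correlation distances (see above).
* The σ = 4 / c_true = 11 selection by cv_new is optimiser-dependent; this
  implementation's multi-restart minimisation typically selects larger c.
* No spatial regularisation: memberships ignore voxel adjacency, so
  isolated supra-threshold voxels are expected and are reported by the
  granulometry rather than suppressed.
* The generator's i.i.d. Gaussian noise is a lower bound on the difficulty
  of real fMRI noise.
* `cMax` beyond √n triggers a warning, not an error; partitions that fine
  are rarely meaningful but occasionally useful for diagnostics.
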