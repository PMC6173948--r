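# fcmvalid

Unsupervised fuzzy c-means clustering of voxel time-courses with the full
toolbox needed to answer the hard question: *how many clusters are actually
in the data?*

`fcmvalid` is aimed at analysts of fMRI-like data (n time-courses of p
points each, typically voxels by scans) who use model-free clustering. It
provides:

* **fuzzy c-means** (FCM) with a correlation-based similarity: the
  square-root-modified hyperbolic distance
  D = (√|CC| − CC) / (√|CC| + CC), which spreads mid-to-high correlations
  apart by larger ratios than the classic (1 − CC)/(1 + CC) transform
  (both are available), with multi-restart initialisation and a compiled
  inner loop;
* **all the compactness/separation building blocks** of the validity
  literature — fuzzy cardinality n₍m,j₎ and variation σ₍m,j₎, π₍m,1₎,
  π₍m,m₎, FC, K₍m₎, FS, S, SS, the fuzzy overlap FO = FS/FC, the
  between-centroid distances Vdmin/Vdmax, and intra/inter-cluster
  dissimilarity coefficients;
* **eight cluster validity indices** built from them —
  Rezaee-Lelieveldt-Reider, Zahid-Limouri-Essaid, Geva, Kim-Park,
  Pakhira-Bandyopadhyay-Maulik, Wu-Yang, Bouguessa-Wang-Sun, and a
  compactness-separation product index
  CVₙₑw = K₍m₎ · (ID_inter/ID_intra) · (FC/J₁) designed to stay informative
  on noisy data with many clusters;
* an **automated sweep** over candidate cluster counts c, with the
  α-normalisation constants fixed at the top of the sweep, degenerate
  (redundant-centroid) partitions excluded by a sentinel, and the selected
  c reported per index;
* a **synthetic benchmark generator** (weakly correlated Gaussian
  prototypes, replicated and noised, with ground-truth labels) for
  validating recovery, plus the degenerate single-cluster and structureless
  references;
* **granulometry** of crisp 3D cluster maps: 26/18/6-connected region
  sizes and single-voxel counts, with NIfTI input/output and
  design-regressor screening of centroids.

The minimised objective is J₍m₎ = Σᵢ Σⱼ U₍ij₎^m · D₍ij₎², with memberships
U₍ij₎ = 1 / Σₖ (D₍ij₎/D₍ik₎)^{2/(m−1)} and centroids
Vⱼ = Σᵢ U₍ij₎^m Xᵢ / Σᵢ U₍ij₎^m; the degree of fuzziness defaults to
m = 1.5. See the methods vignette
(`vignettes/cluster-validity-methods.Rmd`) for every convention and design
choice.

## Worked example

Generate a benchmark dataset with 5 known clusters, sweep c = 2..12, and
let the indices vote:

```r
library(fcmvalid)

ds <- generateClusterDataset(cTrue = 5, n = 1000, p = 100, sigma = 1,
                             seed = 42)
ds
#> SyntheticDataset: 1000 voxels x 100 time points, 5 true clusters, sigma = 1

sw <- fcmSweep(ds, cMin = 2, cMax = 12, nInit = 10, seed = 42)
sw
#> SweepResult: c = 2..12, m = 1.5, 10 restarts, seed 42
#>   selected number of clusters per index:
#>     cv_rlr  5
#>     cv_zle  5
#>     cv_gv   5
#>     cv_kp   5
#>     cv_pbm  5
#>     cv_wy   5
#>     cv_bws  5
#>     cv_new  5

round(indexTable(sw)[, c("c", "cv_rlr", "cv_gv", "cv_bws", "cv_new")], 4)
#>   c cv_rlr    cv_gv    cv_bws    cv_new
#>   2 1.2181 242.4850  544378.3  198.8131
#>   3 0.4675 258.4982  909642.0  416.4947
#>   4 0.2545 273.8657 1513615.9  202.9401
#>   5 0.0936 454.0387 2414337.4 4075.0394
#>   6     NA       NA        NA        NA
#>   ...
```

Every index is optimised (minimised for cv_rlr and cv_kp, maximised for the
rest) at the generative count c = 5. Rows beyond c = 5 are `NA`: those
partitions contain redundant (coincident) centroids — a c-partition that is
really the 5-partition in disguise — and the degenerate-partition sentinel
removes them from the vote. The winning partition itself:

```r
sw@partitions[["5"]]
#> FuzzyPartition: 1000 voxels, 5 clusters, m = 1.5, modified distance
#>   6 iterations (converged), final J_m = 8.2676
```

Screening the fitted centroids against a known regressor (here the first
true prototype) flags exactly the matching cluster:

```r
correlateWithDesign(centroids(sw@partitions[["5"]]), prototypes(ds)[1, ])
#>   cluster      r p.value ofInterest
#> 1       1 -0.033   0.745      FALSE
#> 2       2  0.066   0.513      FALSE
#> 3       3  0.998   0.000       TRUE
#> 4       4  0.095   0.350      FALSE
#> 5       5  0.025   0.806      FALSE
```

For real volumes, `readNiftiTimecourses("bold.nii.gz", "mask.nii.gz")`
produces the input matrix, `crispPartition()` + `regionSizes()` give the
spatial granulometry of any fitted partition, and
`Rscript inst/scripts/fcmcv.R <generate|sweep|scan-m|granulometry> ...`
exposes the same pipeline from the shell.

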