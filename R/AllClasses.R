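#' @useDynLib fcmvalid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor pt runif rnorm var sd
#' @importFrom utils write.table read.table
NULL

#' Converged fuzzy c-means state for one number of clusters
#'
#' Holds the membership matrix `U` (n voxels x c clusters, rows summing to 1),
#' the centroid matrix `V` (c x p, in the units of the data), the
#' voxel-to-centroid distance matrix `D` used by the objective, the degree of
#' fuzziness `m`, and the per-iteration objective history.
#'
#' @slot U numeric matrix, n x c memberships in \[0, 1\], rows sum to 1.
#' @slot V numeric matrix, c x p centroids (prototype time-courses).
#' @slot D numeric matrix, n x c correlation-based distances (>= 0).
#' @slot m numeric(1), degree of fuzziness (> 1).
#' @slot JHistory numeric, objective value per iteration (non-increasing).
#' @slot nIter integer(1), iterations run.
#' @slot converged logical(1), whether the membership change fell below
#'   tolerance before the iteration cap.
#' @slot seed integer(1), seed of the initialisation that produced this state.
#' @slot restartJ numeric, final objective of every restart (when the state
#'   came out of [multiInitFCM()]).
#' @slot distance character(1), `"modified"` or `"hyperbolic"`.
#' @exportClass FuzzyPartition
setClass("FuzzyPartition",
  representation(U = "matrix", V = "matrix", D = "matrix", m = "numeric",
                 JHistory = "numeric", nIter = "integer",
                 converged = "logical", seed = "integer",
                 restartJ = "numeric", distance = "character"))

setValidity("FuzzyPartition", function(object) {
  msg <- character()
  if (nrow(object@U) != nrow(object@D) || ncol(object@U) != ncol(object@D))
    msg <- c(msg, "U and D must have identical dimensions")
  if (ncol(object@U) != nrow(object@V))
    msg <- c(msg, "ncol(U) must equal nrow(V)")
  if (any(object@U < -1e-12) || any(object@U > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (any(abs(rowSums(object@U) - 1) > 1e-9))
    msg <- c(msg, "membership rows must sum to 1")
  if (object@m <= 1)
    msg <- c(msg, "fuzziness m must exceed 1")
  if (any(object@D < 0))
    msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Compactness and separation measures of one fuzzy partition
#'
#' All building blocks from which cluster validity indices are assembled:
#' fuzzy cardinalities and variations per cluster, the compactness scalars
#' (pi_m1, pi_mm, FC), the separation scalars (K_m, K_1, FS, S, SS, FO),
#' between-centroid distances (Vdmin, Vdmax, per-cluster minima), the intra-
#' and inter-cluster dissimilarity coefficients, and the objectives J_1, J_m.
#'
#' @slot n1,nm numeric(c), fuzzy cardinalities with exponents 1 and m.
#' @slot sigma1,sigmam numeric(c), fuzzy variations with exponents 1 and m.
#' @slot piM1,piMM,FC numeric(1), compactness scalars.
#' @slot Km,K1,FS,S,SS,FO numeric(1), separation scalars (`NA` when the
#'   configuration is degenerate, e.g., all centroids coincide).
#' @slot Vdmin,Vdmax numeric(1), extreme between-centroid distances.
#' @slot VdminPerCluster numeric(c), nearest-other-centroid distance.
#' @slot IDintra,IDinter numeric(1), dissimilarity coefficients.
#' @slot J1,Jm numeric(1), objective with exponents 1 and m.
#' @slot globalMean numeric(p), grand mean time-course of the data.
#' @slot sigmaXNorm numeric(1), Euclidean norm of the per-time-point
#'   variance vector of the data.
#' @slot dataScale numeric(1), sqrt of the summed per-time-point variances:
#'   the natural length scale of the centroid space, against which
#'   coincident (redundant) centroids are detected.
#' @slot n,c,m numeric(1), problem size and fuzziness bookkeeping.
#' @exportClass MeasureSet
setClass("MeasureSet",
  representation(n1 = "numeric", nm = "numeric",
                 sigma1 = "numeric", sigmam = "numeric",
                 piM1 = "numeric", piMM = "numeric", FC = "numeric",
                 Km = "numeric", K1 = "numeric", FS = "numeric",
                 S = "numeric", SS = "numeric", FO = "numeric",
                 Vdmin = "numeric", Vdmax = "numeric",
                 VdminPerCluster = "numeric",
                 IDintra = "numeric", IDinter = "numeric",
                 J1 = "numeric", Jm = "numeric",
                 globalMean = "numeric", sigmaXNorm = "numeric",
                 dataScale = "numeric",
                 n = "numeric", c = "numeric", m = "numeric"))

setValidity("MeasureSet", function(object) {
  msg <- character()
  if (length(object@n1) != object@c)
    msg <- c(msg, "n1 must have one entry per cluster")
  if (abs(sum(object@n1) - object@n) > 1e-6 * object@n)
    msg <- c(msg, "fuzzy cardinalities n1 must sum to n")
  if (is.finite(object@Vdmin) && is.finite(object@Vdmax) &&
      object@Vdmin > object@Vdmax + 1e-12)
    msg <- c(msg, "Vdmin cannot exceed Vdmax")
  if (length(msg)) msg else TRUE
})

#' Result of an unsupervised sweep over candidate cluster counts
#'
#' One record per c in `[cMin, cMax]`: the best-of-restarts partition, its
#' [MeasureSet-class], and the eight validity index values (computed with the
#' alpha constants fixed at `cMax`). `cOpt` holds the selected number of
#' clusters per index.
#'
#' @slot partitions list of [FuzzyPartition-class], named by c.
#' @slot measures list of [MeasureSet-class], named by c.
#' @slot indexTable data.frame, one row per c, one column per index.
#' @slot measureTable data.frame, one row per c, one column per measure.
#' @slot alphas named numeric, alpha constants fixed at `cMax`.
#' @slot cOpt named integer, selected c per index.
#' @slot cMin,cMax integer(1), sweep bounds.
#' @slot m numeric(1), degree of fuzziness.
#' @slot nInit integer(1), random restarts per c.
#' @slot seed integer(1), base seed.
#' @slot distance character(1), distance variant used.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(partitions = "list", measures = "list",
                 indexTable = "data.frame", measureTable = "data.frame",
                 alphas = "numeric", cOpt = "integer",
                 cMin = "integer", cMax = "integer", m = "numeric",
                 nInit = "integer", seed = "integer", distance = "character"))

setValidity("SweepResult", function(object) {
  msg <- character()
  expected <- object@cMax - object@cMin + 1L
  if (length(object@partitions) != expected)
    msg <- c(msg, "one partition per c in [cMin, cMax] is required")
  cs <- as.integer(names(object@partitions))
  sizes <- vapply(object@partitions, function(p) ncol(p@U), integer(1))
  if (!identical(unname(sizes), cs))
    msg <- c(msg, "each record's cluster count must equal its key")
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark dataset with ground truth
#'
#' A generated voxel-by-time matrix together with the true cluster labels,
#' the prototype time-courses each cluster was replicated from, and the
#' additive Gaussian noise level.
#'
#' @slot X numeric matrix, n x p time-courses.
#' @slot labels integer(n), true cluster assignment per voxel.
#' @slot prototypes numeric matrix, cTrue x p prototype time-courses.
#' @slot sigma numeric(1), noise standard deviation.
#' @slot cTrue integer(1), true number of clusters.
#' @slot seed integer(1), generator seed.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(X = "matrix", labels = "integer", prototypes = "matrix",
                 sigma = "numeric", cTrue = "integer", seed = "integer"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@X))
    msg <- c(msg, "one label per row of X is required")
  tab <- tabulate(object@labels, nbins = object@cTrue)
  if (sum(tab) != nrow(object@X))
    msg <- c(msg, "label counts must sum to n")
  if (ncol(object@prototypes) != ncol(object@X))
    msg <- c(msg, "prototypes and X must share the time dimension")
  if (length(msg)) msg else TRUE
})
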