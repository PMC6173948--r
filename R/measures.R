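#' Fuzzy cardinality per cluster
#'
#' n_{m,j} = sum_i U_ij^m. With exponent 1 this is the fuzzy cardinality
#' (the "soft size" of each cluster; the per-cluster values sum to n);
#' with exponent 2 it is the fuzzy partition of the cluster.
#'
#' @param U numeric matrix, n x c memberships.
#' @param mExp numeric(1), exponent >= 1.
#' @return numeric(c).
#' @export
fuzzyCardinality <- function(U, mExp = 1) {
  if (mExp < 1) stop("exponent must be >= 1")
  colSums(U^mExp)
}

#' Fuzzy variation per cluster
#'
#' sigma_{m,j} = sum_i U_ij^m D_ij^2, the membership-weighted squared
#' scatter of the voxels around centroid j.
#'
#' @inheritParams fuzzyCardinality
#' @param D numeric matrix, n x c distances.
#' @return numeric(c).
#' @export
fuzzyVariation <- function(U, D, mExp = 1) {
  if (!all(dim(U) == dim(D)))
    stop("U and D must have identical dimensions")
  colSums(U^mExp * D^2)
}

#' Fuzzy compactness scalars
#'
#' The three compactness (cohesiveness) measures of a fuzzy partition:
#' pi_m1 = sum_j sigma_{m,j} / n_{1,j}, pi_mm = sum_j sigma_{m,j} / n_{m,j},
#' and FC = sum_i (max_j U_ij)^2 / sum_i max_j U_ij. FC equals 1 for a crisp
#' partition and 1/c for the fuzziest one.
#'
#' @param partition a [FuzzyPartition-class].
#' @return named list with `piM1`, `piMM`, `FC`.
#' @export
compactnessMeasures <- function(partition) {
  U <- partition@U; D <- partition@D; m <- partition@m
  n1 <- fuzzyCardinality(U, 1)
  nm <- fuzzyCardinality(U, m)
  sm <- fuzzyVariation(U, D, m)
  mx <- U[cbind(seq_len(nrow(U)), max.col(U, ties.method = "first"))]
  list(piM1 = sum(sm / n1), piMM = sum(sm / nm), FC = sum(mx^2) / sum(mx))
}

#' Fuzzy separation scalars
#'
#' The separation (isolation) measures of a fuzzy partition, all based on
#' Euclidean norms in the p-dimensional centroid space:
#' K_m = sum_j n_{m,j} ||V_j - Xbar||^2 (and K_1 with exponent 1),
#' FS = the summed pairwise shared-membership ratio over unordered cluster
#' pairs, S = mean squared centroid-to-grand-mean norm,
#' SS = sum_j 1 / sum_k ||V_j - V_k|| (the k = j term is zero and harmless),
#' and the fuzzy overlap FO = FS / FC.
#'
#' The grand mean Xbar is, by default, the scalar mean over all voxels and
#' time points, broadcast over time (`reference = "grandMean"`). On a fuzzy
#' partition without structure, every centroid converges onto the mean
#' time-course itself, so referencing that vector would leave K_m and S at
#' the level of the convergence residual — pure numerical noise — whereas
#' the scalar grand mean keeps them on the scale of the signal and yields
#' the expected closed forms (K_m tracking c^(1-m) on structureless data,
#' S independent of c). The mean-time-course convention remains available
#' as `reference = "meanTimecourse"`.
#'
#' @param partition a [FuzzyPartition-class].
#' @param globalMean numeric(p), the mean time-course of the data the
#'   partition was fitted to (its scalar mean is the grand mean).
#' @param norm `"euclidean"` (default; the convention the source indices
#'   were defined with) or `"correlation"` (the modified correlation
#'   distance, matching the clustering metric; always referenced to the
#'   mean time-course, since correlation with a constant is undefined).
#' @param reference `"grandMean"` (default) or `"meanTimecourse"`; see
#'   Details.
#' @return named list with `Km`, `K1`, `FS`, `S`, `SS`, `FO`. `SS` is `NA`
#'   (degenerate) when all centroids coincide.
#' @export
separationMeasures <- function(partition, globalMean,
                               norm = c("euclidean", "correlation"),
                               reference = c("grandMean",
                                             "meanTimecourse")) {
  norm <- match.arg(norm)
  reference <- match.arg(reference)
  U <- partition@U; V <- partition@V; m <- partition@m
  c <- ncol(U)
  ref <- if (reference == "grandMean")
    rep(mean(globalMean), ncol(V)) else globalMean
  d2 <- if (norm == "euclidean") rowSums(sweep(V, 2, ref)^2)
        else as.numeric(modifiedDistance(
          pearsonCorrelations(V, matrix(globalMean, 1))))^2
  n1 <- fuzzyCardinality(U, 1)
  nm <- fuzzyCardinality(U, m)
  Km <- sum(nm * d2)
  K1 <- sum(n1 * d2)
  S <- mean(d2)
  pd <- .centroidPairDist(V, norm)
  rs <- rowSums(pd)
  SS <- if (any(rs == 0)) NA_real_ else sum(1 / rs)
  FS <- 0
  for (j in seq_len(c - 1)) {
    for (k in seq(j + 1, c)) {
      mn <- pmin(U[, j], U[, k])
      s1 <- sum(mn)
      if (s1 > 0) FS <- FS + sum(mn^2) / s1
    }
  }
  cm <- compactnessMeasures(partition)
  list(Km = Km, K1 = K1, FS = FS, S = S, SS = SS, FO = FS / cm$FC)
}

#' Between-centroid distance summaries
#'
#' Minimum and maximum Euclidean distance over unordered distinct centroid
#' pairs, plus each cluster's distance to its nearest other centroid. A
#' (near-)zero minimum flags redundant clusters with coincident centroids.
#'
#' @param V numeric matrix, c x p centroids with c >= 2.
#' @param norm `"euclidean"` (default) or `"correlation"`; see
#'   [separationMeasures()].
#' @return named list with `Vdmin`, `Vdmax`, `VdminPerCluster` (numeric(c)).
#' @export
centroidDistances <- function(V, norm = c("euclidean", "correlation")) {
  norm <- match.arg(norm)
  V <- as.matrix(V)
  if (nrow(V) < 2) stop("at least two centroids are required")
  pd <- .centroidPairDist(V, norm)
  diag(pd) <- Inf
  perCluster <- apply(pd, 1, min)
  off <- pd[upper.tri(pd)]
  list(Vdmin = min(off), Vdmax = max(off),
       VdminPerCluster = unname(perCluster))
}

# pairwise centroid distance matrix under the selected norm
.centroidPairDist <- function(V, norm) {
  if (norm == "euclidean") return(as.matrix(stats::dist(V)))
  pd <- modifiedDistance(pearsonCorrelations(V, V))
  diag(pd) <- 0
  pd
}

#' Intra- and inter-cluster dissimilarity coefficients
#'
#' Two separation measures built from fuzzy cardinalities and variations
#' with exponent 1:
#' ID_intra = max_j ((n - n_{1,j}) / n_{1,j} * sigma_{1,j} /
#' sum_{k != j} sigma_{1,k}) and
#' ID_inter = min_j (min_{k != j} sigma_{1,k} / sigma_{1,j}).
#' Small ID_intra means voxels close to a cluster are well isolated from
#' those far from it; large ID_inter means small fuzzy overlap. Designed to
#' stay informative on noisy data with many clusters.
#'
#' @param U numeric matrix, n x c memberships (c >= 2).
#' @param D numeric matrix, n x c distances.
#' @return named list with `IDintra`, `IDinter`; both `NA` (degenerate) if
#'   any cluster has zero fuzzy variation.
#' @export
dissimilarityCoefficients <- function(U, D) {
  if (ncol(U) < 2) stop("at least two clusters are required")
  n <- nrow(U)
  n1 <- fuzzyCardinality(U, 1)
  s1 <- fuzzyVariation(U, D, 1)
  if (any(s1 == 0))
    return(list(IDintra = NA_real_, IDinter = NA_real_))
  tot <- sum(s1)
  IDintra <- max((n - n1) / n1 * s1 / (tot - s1))
  c <- ncol(U)
  IDinter <- min(vapply(seq_len(c),
                        function(j) min(s1[-j]) / s1[j], numeric(1)))
  list(IDintra = IDintra, IDinter = IDinter)
}

#' All compactness and separation measures of one partition
#'
#' Evaluates every building block used by the validity indices on a
#' converged partition and the data it was fitted to, returning them in a
#' single [MeasureSet-class].
#'
#' @param partition a [FuzzyPartition-class].
#' @param X numeric matrix, the n x p data the partition was fitted to.
#' @param norm `"euclidean"` (default) or `"correlation"`; the norm used for
#'   all centroid-space separation measures. The Euclidean default is the
#'   convention the source indices were defined with and the one that
#'   reproduces the recovery benchmark.
#' @param reference `"grandMean"` (default) or `"meanTimecourse"`; the
#'   centroid-space reference point, see [separationMeasures()].
#' @return a [MeasureSet-class].
#' @export
computeMeasures <- function(partition, X,
                            norm = c("euclidean", "correlation"),
                            reference = c("grandMean", "meanTimecourse")) {
  norm <- match.arg(norm)
  reference <- match.arg(reference)
  X <- as.matrix(X)
  U <- partition@U; D <- partition@D; m <- partition@m
  if (nrow(X) != nrow(U))
    stop("X and the partition disagree on the number of voxels")
  n <- nrow(U); c <- ncol(U)
  xbar <- colMeans(X)
  # sigma_X: the p-vector of per-time-point variances of the whole data set
  sigmaX <- colSums(sweep(X, 2, xbar)^2) / (n - 1)
  cm <- compactnessMeasures(partition)
  sm <- separationMeasures(partition, xbar, norm, reference)
  cd <- centroidDistances(partition@V, norm)
  id <- dissimilarityCoefficients(U, D)
  s1 <- fuzzyVariation(U, D, 1)
  new("MeasureSet",
      n1 = fuzzyCardinality(U, 1), nm = fuzzyCardinality(U, m),
      sigma1 = s1, sigmam = fuzzyVariation(U, D, m),
      piM1 = cm$piM1, piMM = cm$piMM, FC = cm$FC,
      Km = sm$Km, K1 = sm$K1, FS = sm$FS, S = sm$S, SS = sm$SS, FO = sm$FO,
      Vdmin = cd$Vdmin, Vdmax = cd$Vdmax,
      VdminPerCluster = cd$VdminPerCluster,
      IDintra = id$IDintra, IDinter = id$IDinter,
      J1 = sum(s1), Jm = fcmObjective(U, D, m),
      globalMean = xbar, sigmaXNorm = sqrt(sum(sigmaX^2)),
      dataScale = sqrt(sum(sigmaX)),
      n = n, c = c, m = m)
}

#' Flatten a MeasureSet to a one-row data frame
#'
#' Scalar measures only (per-cluster vectors are dropped); used to build the
#' per-c measure table written alongside sweep results.
#'
#' @param ms a [MeasureSet-class].
#' @return one-row `data.frame`.
#' @export
measureRow <- function(ms) {
  data.frame(c = ms@c, piM1 = ms@piM1, piMM = ms@piMM, FC = ms@FC,
             Km = ms@Km, K1 = ms@K1, FS = ms@FS, S = ms@S, SS = ms@SS,
             FO = ms@FO, Vdmin = ms@Vdmin, Vdmax = ms@Vdmax,
             IDintra = ms@IDintra, IDinter = ms@IDinter,
             J1 = ms@J1, Jm = ms@Jm)
}
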