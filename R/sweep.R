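#' Unsupervised sweep over candidate numbers of clusters
#'
#' Runs multi-restart fuzzy c-means for every c in `[cMin, cMax]`, evaluates
#' all compactness/separation measures on each best-of-restarts partition,
#' fixes the alpha normalisation constants on the c = `cMax` partition, and
#' then evaluates the eight validity indices and the selected c per index.
#' The whole sweep is deterministic given `seed` (restart k at any c uses
#' `seed + k - 1`).
#'
#' @param X numeric matrix, n x p time-courses, or a
#'   [SyntheticDataset-class].
#' @param cMin,cMax integer, sweep bounds, 2 <= cMin <= cMax; a warning is
#'   issued when cMax exceeds sqrt(n), the usual upper bound for a
#'   meaningful partition.
#' @param m numeric(1), degree of fuzziness; default 1.5.
#' @param nInit integer(1), random restarts per c; default 10.
#' @param seed integer(1), base seed.
#' @param distance `"modified"` or `"hyperbolic"`.
#' @param redundancyTol numeric(1), relative threshold below which the
#'   smallest between-centroid distance marks a partition as having
#'   redundant (coincident) centroids; see [computeIndexPanel()].
#'   Default 1e-3.
#' @param norm `"euclidean"` (default) or `"correlation"`; norm for the
#'   centroid-space separation measures, see [computeMeasures()].
#' @param ... further arguments passed to [runFCM()] (e.g., `tol`,
#'   `maxIter`, `standardize`).
#' @return a [SweepResult-class]. An index whose values are degenerate at
#'   every c (possible on structureless or single-cluster data) gets
#'   `NA` in the `cOpt` slot rather than aborting the sweep.
#' @examples
#' ds <- generateClusterDataset(cTrue = 3, n = 120, p = 40, sigma = 1,
#'                              seed = 7)
#' sw <- fcmSweep(ds, cMin = 2, cMax = 6, nInit = 2, seed = 7)
#' optimalClusters(sw)
#' @export
fcmSweep <- function(X, cMin = 2L, cMax, m = 1.5, nInit = 10L, seed = 1L,
                     distance = c("modified", "hyperbolic"),
                     redundancyTol = 1e-3,
                     norm = c("euclidean", "correlation"), ...) {
  distance <- match.arg(distance)
  norm <- match.arg(norm)
  if (is(X, "SyntheticDataset")) X <- X@X
  X <- as.matrix(X)
  n <- nrow(X)
  cMin <- as.integer(cMin); cMax <- as.integer(cMax)
  if (cMin < 2 || cMin > cMax) stop("need 2 <= cMin <= cMax")
  if (cMax > ceiling(sqrt(n)))
    warning("cMax exceeds sqrt(n); partitions beyond that are rarely meaningful")
  cs <- seq(cMin, cMax)
  partitions <- vector("list", length(cs))
  measures <- vector("list", length(cs))
  names(partitions) <- names(measures) <- cs
  for (i in seq_along(cs)) {
    p <- multiInitFCM(X, cs[i], m = m, nInit = nInit, seed = seed,
                      distance = distance, ...)
    partitions[[i]] <- p
    measures[[i]] <- computeMeasures(p, X, norm)
  }
  alphas <- alphaAtCmax(measures[[length(cs)]])
  panel <- t(vapply(measures, computeIndexPanel, numeric(8),
                    alphas = alphas, redundancyTol = redundancyTol))
  indexTable <- data.frame(c = cs, panel, row.names = NULL)
  measureTable <- do.call(rbind, lapply(measures, measureRow))
  rownames(measureTable) <- NULL
  cOpt <- vapply(names(cvDirections()), function(ix)
    tryCatch(selectCOpt(indexTable[[ix]], cs, ix),
             error = function(e) NA_integer_), integer(1))
  new("SweepResult", partitions = partitions, measures = measures,
      indexTable = indexTable, measureTable = measureTable,
      alphas = alphas, cOpt = cOpt, cMin = cMin, cMax = cMax, m = m,
      nInit = as.integer(nInit), seed = as.integer(seed),
      distance = distance)
}

#' Correlate centroids with an experimental design
#'
#' Pearson correlation of each centroid (prototype time-course) with a
#' design regressor (e.g., a boxcar encoding a block paradigm), with a
#' two-sided t-test p-value per centroid. Clusters whose centroid correlates
#' at or above `threshold` with p below `pThreshold` are flagged as
#' task-related clusters of interest.
#'
#' @param V numeric matrix, c x p centroids.
#' @param design numeric(p) regressor; must not be constant.
#' @param threshold numeric(1), correlation cut-off for the flag;
#'   default 0.5.
#' @param pThreshold numeric(1), significance cut-off; default 0.001.
#' @return data.frame with `cluster`, `r`, `p.value`, `ofInterest`.
#' @export
correlateWithDesign <- function(V, design, threshold = 0.5,
                                pThreshold = 0.001) {
  V <- as.matrix(V)
  design <- as.numeric(design)
  if (length(design) != ncol(V))
    stop("design length must equal the number of time points")
  if (sd(design) == 0) stop("design regressor is constant; correlation undefined")
  r <- as.numeric(pearsonCorrelations(V, matrix(design, 1)))
  p <- ncol(V)
  tv <- r * sqrt((p - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * pt(abs(tv), df = p - 2, lower.tail = FALSE)
  data.frame(cluster = seq_len(nrow(V)), r = r, p.value = pv,
             ofInterest = abs(r) >= threshold & pv < pThreshold)
}

#' Sensitivity of cluster-count selection to the degree of fuzziness
#'
#' Repeats [fcmSweep()] on the same data over a grid of fuzziness values and
#' tabulates the selected number of clusters per index per m. Useful for
#' checking how robust a selection is: soft memberships flatten toward 1/c
#' as m grows, and selections on noisy data with many clusters degrade
#' first.
#'
#' @param X data matrix or [SyntheticDataset-class].
#' @param mGrid numeric vector of fuzziness values (> 1);
#'   default `c(1.2, 1.5, 2, 2.5)`.
#' @param ... arguments passed to [fcmSweep()] (`cMin`, `cMax`, `nInit`,
#'   `seed`, ...).
#' @return data.frame, one row per m, one column per index holding the
#'   selected c.
#' @export
mSensitivityScan <- function(X, mGrid = c(1.2, 1.5, 2, 2.5), ...) {
  if (any(mGrid <= 1)) stop("all fuzziness values must exceed 1")
  rows <- lapply(mGrid, function(m) {
    sw <- fcmSweep(X, m = m, ...)
    data.frame(m = m, t(sw@cOpt))
  })
  do.call(rbind, rows)
}
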