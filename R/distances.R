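#' Pearson correlations between time-courses and centroids
#'
#' Computes the n x c matrix of sample Pearson correlation coefficients
#' between each row of `X` (a voxel time-course) and each row of `V` (a
#' centroid / prototype time-course). A constant (zero-variance) time-course
#' carries no temporal signal; its correlations are defined as 0, which the
#' distance transforms map to the maximal finite distance, and a warning is
#' emitted.
#'
#' @param X numeric matrix, n x p time-courses.
#' @param V numeric matrix, c x p centroids; p must match `X` and be >= 3.
#' @return numeric matrix, n x c, entries in \[-1, 1\].
#' @seealso [hyperbolicDistance()], [modifiedDistance()],
#'   [correlationDistance()]
#' @export
pearsonCorrelations <- function(X, V) {
  X <- as.matrix(X); V <- as.matrix(V)
  if (ncol(X) != ncol(V))
    stop("X and V must have the same number of time points")
  if (ncol(X) < 3)
    stop("at least 3 time points are required for a meaningful correlation")
  Zx <- .standardizeRows(X, warn = TRUE)
  Zv <- .standardizeRows(V, warn = TRUE)
  CC <- tcrossprod(Zx, Zv)
  # numeric guard: the product can stray past +-1 by machine epsilon
  CC[CC > 1] <- 1
  CC[CC < -1] <- -1
  CC
}

# rows centred and scaled to unit sum of squares, zero-variance rows zeroed
.standardizeRows <- function(M, warn = FALSE) {
  Z <- M - rowMeans(M)
  ss <- sqrt(rowSums(Z^2))
  bad <- ss == 0
  if (any(bad)) {
    if (warn)
      warning(sum(bad), " constant time-course(s): correlation set to 0")
    ss[bad] <- 1
    Z[bad, ] <- 0
  }
  Z / ss
}

# shared clamp keeping the correlation away from the cc = -1 pole so the
# membership update never receives an infinite distance
.CC_CLAMP <- 1e-6

.checkCC <- function(cc) {
  if (any(!is.finite(cc)))
    stop("correlation values must be finite")
  if (any(cc < -1 - 1e-8) || any(cc > 1 + 1e-8))
    stop("correlation values must lie in [-1, 1]")
  pmin(pmax(cc, -1 + .CC_CLAMP), 1)
}

#' Hyperbolic correlation distance
#'
#' Maps a Pearson correlation cc to the distance (1 - cc) / (1 + cc):
#' 0 for perfectly correlated signals, 1 for uncorrelated ones, growing
#' without bound as cc approaches -1. The correlation is clamped to
#' `[-1 + 1e-6, 1]` so the result stays finite.
#'
#' @param cc numeric vector or matrix of correlations in \[-1, 1\].
#' @return distances of the same shape as `cc`, all >= 0.
#' @export
hyperbolicDistance <- function(cc) {
  cc <- .checkCC(cc)
  (1 - cc) / (1 + cc)
}

#' Square-root-modified hyperbolic correlation distance
#'
#' Maps a Pearson correlation cc to (sqrt(|cc|) - cc) / (sqrt(|cc|) + cc).
#' Because sqrt(x) >= x on \[0, 1\], this transform spreads mid-to-high
#' correlations further apart than [hyperbolicDistance()] does, increasing
#' discrimination exactly where time-courses in low-noise data live. The
#' 0/0 form at cc = 0 is defined by continuity as 1 (both one-sided limits
#' equal 1), and cc is clamped to `[-1 + 1e-6, 1]` as in the hyperbolic
#' transform.
#'
#' @inheritParams hyperbolicDistance
#' @return distances of the same shape as `cc`, all >= 0; strictly
#'   decreasing in cc.
#' @export
modifiedDistance <- function(cc) {
  cc <- .checkCC(cc)
  s <- sqrt(abs(cc))
  d <- (s - cc) / (s + cc)
  d[cc == 0] <- 1
  d
}

#' Correlation distance matrix between time-courses and centroids
#'
#' Convenience wrapper: Pearson correlations via [pearsonCorrelations()]
#' followed by one of the two correlation-to-distance transforms.
#'
#' @inheritParams pearsonCorrelations
#' @param variant `"modified"` (default, the square-root transform) or
#'   `"hyperbolic"`.
#' @return numeric matrix, n x c, of non-negative distances.
#' @export
correlationDistance <- function(X, V, variant = c("modified", "hyperbolic")) {
  variant <- match.arg(variant)
  cc <- pearsonCorrelations(X, V)
  if (variant == "modified") modifiedDistance(cc) else hyperbolicDistance(cc)
}
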