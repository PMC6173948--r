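#' Fuzzy c-means objective function
#'
#' The membership-weighted sum of squared distances
#' J_m = sum_i sum_j U_ij^m D_ij^2 that fuzzy c-means minimises.
#'
#' @param U numeric matrix, n x c memberships.
#' @param D numeric matrix, n x c distances.
#' @param m numeric(1), degree of fuzziness (> 1 for clustering; exponent 1
#'   is accepted since J_1 is itself a reported measure).
#' @return numeric(1), the objective value (>= 0).
#' @export
fcmObjective <- function(U, D, m) {
  if (!all(dim(U) == dim(D)))
    stop("U and D must have identical dimensions")
  if (m < 1) stop("fuzziness exponent must be >= 1")
  sum(U^m * D^2)
}

#' Membership update of fuzzy c-means
#'
#' Recomputes memberships from distances:
#' U_ij = 1 / sum_k (D_ij / D_ik)^(2/(m-1)). A voxel at zero distance from
#' one or more centroids receives membership 1 split equally across the
#' coincident centroids (the standard singularity convention).
#'
#' @param D numeric matrix, n x c non-negative finite distances.
#' @param m numeric(1), degree of fuzziness (> 1).
#' @return numeric matrix, n x c memberships; rows sum to 1.
#' @export
updateMemberships <- function(D, m) {
  if (m <= 1) stop("fuzziness m must exceed 1")
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and non-negative")
  e <- 2 / (m - 1)
  A <- (1 / D)^e
  U <- A / rowSums(A)
  zero <- which(rowSums(D == 0) > 0)
  for (i in zero) {
    z <- D[i, ] == 0
    U[i, ] <- 0
    U[i, z] <- 1 / sum(z)
  }
  U
}

#' Centroid update of fuzzy c-means
#'
#' Recomputes centroids as membership-weighted means of the raw
#' time-courses: V_j = sum_i U_ij^m X_i / sum_i U_ij^m.
#'
#' @param X numeric matrix, n x p time-courses.
#' @param U numeric matrix, n x c memberships.
#' @param m numeric(1), degree of fuzziness.
#' @return numeric matrix, c x p centroids.
#' @export
updateCentroids <- function(X, U, m) {
  if (nrow(X) != nrow(U))
    stop("X and U must have the same number of rows")
  W <- U^m
  ws <- colSums(W)
  if (any(ws <= 0))
    stop("degenerate cluster: zero total membership weight")
  crossprod(W, X) / ws
}

# random memberships uniform on the row simplex (normalised uniforms)
.initMemberships <- function(n, c, seed) {
  set.seed(seed)
  U <- matrix(runif(n * c), n, c)
  U / rowSums(U)
}

#' Run fuzzy c-means with a correlation-based distance
#'
#' Alternates the centroid update, the correlation-to-distance transform
#' ([modifiedDistance()] by default), and the membership update until the
#' largest absolute membership change falls below `tol` or `maxIter` is
#' reached. Memberships are initialised at random (uniform on the row
#' simplex) from `seed`, so a run is fully reproducible.
#'
#' @param X numeric matrix, n x p time-courses (n >= 2, p >= 3, finite).
#' @param c integer(1), number of clusters, 2 <= c <= n.
#' @param m numeric(1), degree of fuzziness; default 1.5.
#' @param seed integer(1), initialisation seed.
#' @param maxIter integer(1), iteration cap; default 300.
#' @param tol numeric(1), convergence threshold; default 1e-5.
#' @param stopRule `"deltaU"` (stop when max |delta U| < `tol`) or
#'   `"deltaJ"` (stop when the objective improves by less than `tol`, the
#'   classic stopping rule of fuzzy c-means implementations).
#' @param distance `"modified"` or `"hyperbolic"`.
#' @param standardize logical(1); if `TRUE`, rows of `X` are z-scored before
#'   clustering. Irrelevant for the correlation distance itself but it does
#'   change the centroid update, which averages the raw rows. Default
#'   `FALSE`.
#' @return a [FuzzyPartition-class]. Non-convergence at `maxIter` is flagged
#'   in the `converged` slot, not an error.
#' @export
runFCM <- function(X, c, m = 1.5, seed = 1L, maxIter = 300L, tol = 1e-5,
                   stopRule = c("deltaU", "deltaJ"),
                   distance = c("modified", "hyperbolic"),
                   standardize = FALSE) {
  distance <- match.arg(distance)
  stopRule <- match.arg(stopRule)
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 3)
    stop("X must have at least 2 rows and 3 columns")
  if (any(!is.finite(X))) stop("X must be finite")
  if (c < 2 || c > nrow(X)) stop("c must satisfy 2 <= c <= n")
  if (m <= 1) stop("fuzziness m must exceed 1")
  if (standardize) {
    s <- apply(X, 1, sd)
    s[s == 0] <- 1
    X <- (X - rowMeans(X)) / s
  }
  U0 <- .initMemberships(nrow(X), c, seed)
  Xs <- .standardizeRows(X, warn = TRUE)
  fit <- .fcm_fit_cpp(X, Xs, U0, m, as.integer(maxIter), tol,
                      if (distance == "hyperbolic") 1L else 2L, .CC_CLAMP,
                      if (stopRule == "deltaJ") 2L else 1L)
  new("FuzzyPartition", U = fit$U, V = fit$V, D = fit$D, m = m,
      JHistory = as.numeric(fit$J_history), nIter = as.integer(fit$n_iter),
      converged = fit$converged, seed = as.integer(seed),
      restartJ = utils::tail(as.numeric(fit$J_history), 1),
      distance = distance)
}

#' Fuzzy c-means with multiple random restarts
#'
#' Runs [runFCM()] `nInit` times with seeds `seed + 0 .. nInit - 1` and
#' returns the partition with the smallest final objective J_m; the final
#' objective of every restart is recorded in the `restartJ` slot. Random
#' initialisation can land fuzzy c-means in different local minima, so
#' re-running from several starting points and keeping the best fit is the
#' standard guard.
#'
#' @inheritParams runFCM
#' @param nInit integer(1), number of random restarts (>= 1); default 10.
#' @param seed integer(1), base seed; restart k uses `seed + k - 1`.
#' @param ... further arguments passed to [runFCM()].
#' @return the minimum-objective [FuzzyPartition-class].
#' @export
multiInitFCM <- function(X, c, m = 1.5, nInit = 10L, seed = 1L, ...) {
  if (nInit < 1) stop("nInit must be at least 1")
  best <- NULL
  finals <- numeric(nInit)
  for (k in seq_len(nInit)) {
    fit <- runFCM(X, c, m = m, seed = seed + k - 1L, ...)
    finals[k] <- utils::tail(fit@JHistory, 1)
    if (is.null(best) || finals[k] < utils::tail(best@JHistory, 1))
      best <- fit
  }
  best@restartJ <- finals
  best
}
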