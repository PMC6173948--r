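#' Generate weakly correlated prototype time-courses
#'
#' Draws `cTrue` rows of i.i.d. standard normal values of length `p` and
#' rejection-samples row by row until every pairwise Pearson correlation is
#' below `maxAbsCC` in absolute value: each new prototype is redrawn until
#' it satisfies the constraint against all previously accepted ones. (For
#' p = 100 the pairwise correlation of independent normal rows has a
#' standard deviation near 0.1, so a joint redraw of the whole set would
#' essentially never satisfy 55 simultaneous constraints; per-row rejection
#' yields the identical admissible distribution cheaply.)
#'
#' @param cTrue integer(1), number of prototypes (>= 1).
#' @param p integer(1), time points per prototype.
#' @param maxAbsCC numeric(1) in (0, 1), admissibility bound; default 0.1.
#' @param seed integer(1), generator seed.
#' @param budget integer(1), redraw budget per row; default 10000.
#' @return numeric matrix, cTrue x p.
#' @export
generatePrototypes <- function(cTrue, p, maxAbsCC = 0.1, seed = 1L,
                               budget = 10000L) {
  if (cTrue < 1) stop("cTrue must be >= 1")
  if (maxAbsCC <= 0 || maxAbsCC >= 1) stop("maxAbsCC must lie in (0, 1)")
  set.seed(seed)
  P <- matrix(rnorm(p), 1, p)
  while (nrow(P) < cTrue) {
    ok <- FALSE
    for (attempt in seq_len(budget)) {
      cand <- rnorm(p)
      cc <- pearsonCorrelations(P, matrix(cand, 1))
      if (max(abs(cc)) < maxAbsCC) { ok <- TRUE; break }
    }
    if (!ok)
      stop("prototype rejection budget exhausted; p is too small for cTrue")
    P <- rbind(P, cand)
  }
  dimnames(P) <- NULL
  P
}

# equal split of n voxels over cTrue clusters, remainder to the first ones
.defaultSizes <- function(n, cTrue) {
  base <- n %/% cTrue
  sizes <- rep(base, cTrue)
  extra <- n - base * cTrue
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a benchmark dataset with a known number of clusters
#'
#' Emulates the standard recovery benchmark: `cTrue` weakly correlated
#' standard-normal prototype time-courses (see [generatePrototypes()]) are
#' each replicated r_j times (equal split by default, sum r_j = n), and
#' i.i.d. Gaussian noise with standard deviation `sigma` is added to every
#' voxel. At sigma = 1 the structure is easy to recover; sigma = 4 drowns
#' the prototypes (voxel-to-prototype correlation around 0.24) and probes
#' the robustness of validity indices.
#'
#' @param cTrue integer(1), true number of clusters.
#' @param n integer(1), voxels; default 1000.
#' @param p integer(1), time points; default 100.
#' @param sigma numeric(1), noise standard deviation; default 1.
#' @param seed integer(1), generator seed.
#' @param sizes optional integer(cTrue) cluster sizes summing to n.
#' @return a [SyntheticDataset-class].
#' @export
generateClusterDataset <- function(cTrue, n = 1000L, p = 100L, sigma = 1,
                                   seed = 1L, sizes = NULL) {
  if (n < cTrue) stop("n must be at least cTrue")
  if (is.null(sizes)) sizes <- .defaultSizes(n, cTrue)
  if (length(sizes) != cTrue || sum(sizes) != n)
    stop("sizes must have one entry per cluster and sum to n")
  P <- generatePrototypes(cTrue, p, seed = seed)
  labels <- rep(seq_len(cTrue), times = sizes)
  X <- P[labels, , drop = FALSE]
  if (sigma > 0) X <- X + matrix(rnorm(n * p, sd = sigma), n, p)
  new("SyntheticDataset", X = X, labels = as.integer(labels),
      prototypes = P, sigma = sigma, cTrue = as.integer(cTrue),
      seed = as.integer(seed))
}

#' Generate the single-cluster ("null") dataset
#'
#' One prototype replicated n times plus unit-variance Gaussian noise:
#' highly similar voxels with no further structure. Clustering it at any
#' c >= 2 produces near-uniform memberships (1/c) and near-identical
#' centroids — the degenerate regime every validity index must not reward.
#'
#' @param n,p integer(1), dimensions; defaults 1000 x 100.
#' @param seed integer(1), generator seed.
#' @return a [SyntheticDataset-class] with `cTrue = 1`.
#' @export
generateOneCluster <- function(n = 1000L, p = 100L, seed = 1L) {
  generateClusterDataset(1L, n = n, p = p, sigma = 1, seed = seed)
}

#' Generate the structureless ("n-cluster") dataset
#'
#' n i.i.d. standard-normal time-courses: every voxel is its own prototype,
#' so the optimal number of clusters is near n itself. Probes how measures
#' behave on patternless, highly dispersed data.
#'
#' @inheritParams generateOneCluster
#' @return a [SyntheticDataset-class] with `cTrue = n`.
#' @export
generateNCluster <- function(n = 1000L, p = 100L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  new("SyntheticDataset", X = X, labels = seq_len(n), prototypes = X,
      sigma = 1, cTrue = as.integer(n), seed = as.integer(seed))
}

#' Generate the full 22-dataset benchmark suite
#'
#' The complete benchmark: the single-cluster dataset, the structureless
#' dataset, ten datasets with cTrue = 2..11 at sigma = 1, and ten with
#' cTrue = 2..11 at sigma = 4; n = 1000 voxels and p = 100 time points
#' throughout. Each member draws from its own seed derived from `seed`
#' (seed * 1000 + member index), so the suite is reproducible as a unit and
#' per member.
#'
#' @param seed integer(1), base seed.
#' @param n,p integer(1), dimensions shared by all members.
#' @return named list of 22 [SyntheticDataset-class] objects
#'   (`one_cluster`, `n_cluster`, `k02_s1` .. `k11_s1`, `k02_s4` ..
#'   `k11_s4`).
#' @export
generateSuite <- function(seed = 1L, n = 1000L, p = 100L) {
  memberSeed <- function(k) as.integer((as.numeric(seed) * 1000 + k) %%
                                         .Machine$integer.max)
  out <- list(one_cluster = generateOneCluster(n, p, memberSeed(1)),
              n_cluster = generateNCluster(n, p, memberSeed(2)))
  k <- 3
  for (sigma in c(1, 4)) {
    for (cTrue in 2:11) {
      out[[sprintf("k%02d_s%d", cTrue, sigma)]] <-
        generateClusterDataset(cTrue, n = n, p = p, sigma = sigma,
                               seed = memberSeed(k))
      k <- k + 1
    }
  }
  out
}

#' Write a synthetic dataset as delimited text plus a JSON sidecar
#'
#' The matrix goes to `<path>.tsv` (tab-delimited, full double precision);
#' labels, prototypes, sigma, cTrue and seed go to `<path>.json`. The pair
#' round-trips bit-exactly through [readDataset()].
#'
#' @param dataset a [SyntheticDataset-class].
#' @param path file stem (without extension).
#' @return invisibly, the two file paths.
#' @export
writeDataset <- function(dataset, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  writeMatrix(dataset@X, tsv)
  side <- list(labels = dataset@labels,
               prototypes = list(values = sprintf("%.17g",
                                                  dataset@prototypes),
                                 dim = dim(dataset@prototypes)),
               sigma = dataset@sigma, cTrue = dataset@cTrue,
               seed = dataset@seed)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}

#' Read a synthetic dataset written by [writeDataset()]
#'
#' @param path file stem (without extension).
#' @return a [SyntheticDataset-class].
#' @export
readDataset <- function(path) {
  X <- readMatrix(paste0(path, ".tsv"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  P <- matrix(as.numeric(side$prototypes$values),
              side$prototypes$dim[1], side$prototypes$dim[2])
  new("SyntheticDataset", X = X, labels = as.integer(side$labels),
      prototypes = P, sigma = as.numeric(side$sigma),
      cTrue = as.integer(side$cTrue), seed = as.integer(side$seed))
}
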