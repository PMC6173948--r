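#' Crisp 3D label volume from fuzzy memberships
#'
#' Binarises a membership matrix into a label volume: voxel i gets label
#' argmax_j U_ij if its largest membership strictly exceeds `threshold`,
#' and background (0) otherwise. Because membership rows sum to 1, any
#' threshold >= 0.5 guarantees at most one supra-threshold cluster per
#' voxel, so lower thresholds are rejected.
#'
#' @param U numeric matrix, n x c memberships.
#' @param coordinates n x 3 integer matrix of 1-based grid indices.
#' @param gridShape integer(3), volume dimensions.
#' @param threshold numeric(1) >= 0.5; default 0.5 (strict inequality).
#' @return 3D integer array with labels in `{0, 1..c}`.
#' @export
crispPartition <- function(U, coordinates, gridShape, threshold = 0.5) {
  if (threshold < 0.5)
    stop("threshold must be >= 0.5 so each voxel gets at most one label")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(U) || ncol(coordinates) != 3)
    stop("coordinates must be an n x 3 matrix matching U")
  vol <- array(0L, gridShape)
  best <- max.col(U, ties.method = "first")
  mx <- U[cbind(seq_len(nrow(U)), best)]
  keep <- mx > threshold
  vol[coordinates[keep, , drop = FALSE]] <- best[keep]
  vol
}

#' Region sizes of a 3D label volume (morphological granulometry)
#'
#' Finds the spatially connected regions of each cluster label separately
#' (26-connected neighbourhood by default: face, edge and corner adjacency)
#' and reports every region's size in voxels, plus the count of isolated
#' single-voxel regions per cluster and in total.
#'
#' @param volume 3D integer array, 0 = background, j = cluster label.
#' @param connectivity 6, 18 or 26; default 26.
#' @param voxelVolume numeric(1), volume of one voxel in mm^3 (for the
#'   report); default 1.
#' @return list with `regions` (data.frame: `cluster`, `region`,
#'   `size.voxels`, `size.mm3`), `singleVoxelPerCluster` (named integer) and
#'   `singleVoxelTotal` (integer(1)).
#' @export
regionSizes <- function(volume, connectivity = 26, voxelVolume = 1) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  dims <- dim(volume)
  if (length(dims) != 3) stop("a 3D volume is required")
  comp <- .label_components_cpp(as.integer(volume), as.integer(dims),
                                as.integer(connectivity))
  lab <- as.integer(volume)
  inside <- comp > 0
  if (!any(inside)) {
    return(list(regions = data.frame(cluster = integer(), region = integer(),
                                     size.voxels = integer(),
                                     size.mm3 = numeric()),
                singleVoxelPerCluster = integer(), singleVoxelTotal = 0L))
  }
  sizes <- tapply(comp[inside], comp[inside], length)
  regCluster <- tapply(lab[inside], comp[inside], function(x) x[1])
  ord <- order(regCluster, -as.integer(sizes))
  regions <- data.frame(cluster = as.integer(regCluster)[ord],
                        region = as.integer(names(sizes))[ord],
                        size.voxels = as.integer(sizes)[ord])
  regions$size.mm3 <- regions$size.voxels * voxelVolume
  single <- regions[regions$size.voxels == 1, ]
  perCluster <- table(factor(single$cluster,
                             levels = sort(unique(regions$cluster))))
  list(regions = regions,
       singleVoxelPerCluster = c(unclass(perCluster)),
       singleVoxelTotal = nrow(single))
}
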