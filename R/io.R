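#' Write a numeric matrix as tab-delimited text at full precision
#'
#' @param X numeric matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeMatrix <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  apply(X, 1, function(r)
    writeLines(paste(sprintf("%.17g", r), collapse = "\t"), con))
  invisible(path)
}

#' Read a delimited numeric matrix
#'
#' @param path input file (whitespace- or tab-delimited, no header).
#' @return numeric matrix.
#' @export
readMatrix <- function(path) {
  M <- as.matrix(read.table(path, header = FALSE, colClasses = "numeric"))
  dimnames(M) <- NULL
  M
}

#' Flatten a 4D NIfTI volume to a voxel-by-time matrix
#'
#' Reads a 4D image (x, y, z, t) and an optional 3D mask, returning the
#' time-courses of the in-mask voxels as rows, together with the voxel grid
#' coordinates needed to map cluster labels back into the volume.
#'
#' @param imagePath path to a 4D NIfTI file.
#' @param maskPath optional path to a 3D NIfTI mask (non-zero = keep); when
#'   absent, all voxels are kept.
#' @return list with `X` (n x p matrix), `coordinates` (n x 3 integer array
#'   indices, 1-based), `gridShape` (integer(3)), `voxelSize` (mm, per
#'   axis).
#' @export
readNiftiTimecourses <- function(imagePath, maskPath = NULL) {
  img <- RNifti::readNifti(imagePath)
  dm <- dim(img)
  if (length(dm) != 4) stop("a 4D image (x, y, z, t) is required")
  grid <- dm[1:3]
  mask <- if (is.null(maskPath)) array(TRUE, grid) else {
    mk <- RNifti::readNifti(maskPath)
    if (!all(dim(mk)[1:3] == grid)) stop("mask and image grids differ")
    array(mk != 0, grid)
  }
  keep <- which(mask)
  mat <- matrix(img, prod(grid), dm[4])
  coords <- arrayInd(keep, grid)
  pix <- RNifti::pixdim(img)[1:3]
  list(X = mat[keep, , drop = FALSE], coordinates = coords,
       gridShape = grid, voxelSize = pix)
}

#' Write a 3D label volume to NIfTI
#'
#' @param volume 3D integer array (0 = background).
#' @param path output file (.nii or .nii.gz).
#' @param voxelSize numeric(3), voxel edge lengths in mm; default 1.
#' @return invisibly, `path`.
#' @export
writeLabelVolume <- function(volume, path, voxelSize = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write the per-c measure and index tables of a sweep
#'
#' Tab-delimited tables (one row per c) plus a JSON summary with the
#' selected number of clusters per index and the alpha constants — the
#' on-disk record of an unsupervised run.
#'
#' @param sweep a [SweepResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSweepResult <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mt <- file.path(dir, "measures.tsv")
  it <- file.path(dir, "indices.tsv")
  js <- file.path(dir, "summary.json")
  write.table(measureTable(sweep), mt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(indexTable(sweep), it, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(c_opt = as.list(sweep@cOpt), alphas = as.list(sweep@alphas),
         c_min = sweep@cMin, c_max = sweep@cMax, m = sweep@m,
         n_init = sweep@nInit, seed = sweep@seed,
         distance = sweep@distance),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(mt, it, js))
}
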