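#' @rdname FuzzyPartition-class
#' @export
setMethod("memberships", "FuzzyPartition", function(x) x@U)

#' @rdname FuzzyPartition-class
#' @export
setMethod("centroids", "FuzzyPartition", function(x) x@V)

#' @rdname FuzzyPartition-class
#' @export
setMethod("distances", "FuzzyPartition", function(x) x@D)

#' @rdname FuzzyPartition-class
#' @export
setMethod("fuzziness", "FuzzyPartition", function(x) x@m)

#' @rdname FuzzyPartition-class
#' @export
setMethod("objectiveHistory", "FuzzyPartition", function(x) x@JHistory)

#' @rdname FuzzyPartition-class
#' @export
setMethod("nClusters", "FuzzyPartition", function(x) ncol(x@U))

setMethod("show", "FuzzyPartition", function(object) {
  cat(sprintf(
    "FuzzyPartition: %d voxels, %d clusters, m = %g, %s distance\n",
    nrow(object@U), ncol(object@U), object@m, object@distance))
  cat(sprintf("  %d iterations (%s), final J_m = %.6g\n",
              object@nIter,
              if (object@converged) "converged" else "iteration cap reached",
              utils::tail(object@JHistory, 1)))
  invisible(NULL)
})

#' @rdname SweepResult-class
#' @export
setMethod("indexTable", "SweepResult", function(x) x@indexTable)

#' @rdname SweepResult-class
#' @export
setMethod("measureTable", "SweepResult", function(x) x@measureTable)

#' @rdname SweepResult-class
#' @export
setMethod("alphaConstants", "SweepResult", function(x) x@alphas)

#' @rdname SweepResult-class
#' @export
setMethod("optimalClusters", "SweepResult", function(x, index = NULL) {
  if (is.null(index)) return(x@cOpt)
  index <- match.arg(index, names(x@cOpt), several.ok = TRUE)
  x@cOpt[index]
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: c = %d..%d, m = %g, %d restarts, seed %d\n",
              object@cMin, object@cMax, object@m, object@nInit, object@seed))
  cat("  selected number of clusters per index:\n")
  sel <- object@cOpt
  cat(paste(sprintf("    %-7s %s", names(sel), sel), collapse = "\n"), "\n")
  invisible(NULL)
})

#' @rdname SyntheticDataset-class
#' @export
setMethod("timecourses", "SyntheticDataset", function(x) x@X)

#' @rdname SyntheticDataset-class
#' @export
setMethod("trueLabels", "SyntheticDataset", function(x) x@labels)

#' @rdname SyntheticDataset-class
#' @export
setMethod("prototypes", "SyntheticDataset", function(x) x@prototypes)

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d voxels x %d time points, %d true cluster%s, sigma = %g\n",
    nrow(object@X), ncol(object@X), object@cTrue,
    if (object@cTrue == 1) "" else "s", object@sigma))
  invisible(NULL)
})

setMethod("show", "MeasureSet", function(object) {
  cat(sprintf("MeasureSet: c = %d clusters, n = %d, m = %g\n",
              object@c, object@n, object@m))
  cat(sprintf("  compactness: pi_m1 = %.4g, pi_mm = %.4g, FC = %.4g\n",
              object@piM1, object@piMM, object@FC))
  cat(sprintf("  separation:  K_m = %.4g, FS = %.4g, S = %.4g, SS = %.4g\n",
              object@Km, object@FS, object@S, object@SS))
  invisible(NULL)
})
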