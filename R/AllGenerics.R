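#' @rdname FuzzyPartition-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname FuzzyPartition-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname FuzzyPartition-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname FuzzyPartition-class
#' @export
setGeneric("fuzziness", function(x) standardGeneric("fuzziness"))

#' @rdname FuzzyPartition-class
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))

#' @rdname FuzzyPartition-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname SweepResult-class
#' @export
setGeneric("indexTable", function(x) standardGeneric("indexTable"))

#' @rdname SweepResult-class
#' @export
setGeneric("measureTable", function(x) standardGeneric("measureTable"))

#' @rdname SweepResult-class
#' @export
setGeneric("alphaConstants", function(x) standardGeneric("alphaConstants"))

#' @rdname SweepResult-class
#' @param index optional index name to restrict the selection to.
#' @export
setGeneric("optimalClusters",
           function(x, index = NULL) standardGeneric("optimalClusters"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))
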