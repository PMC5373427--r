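#' Accessors for dendrocut classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param object a \linkS4class{MergeSequence},
#'   \linkS4class{ClusterCountEstimate} or \linkS4class{GapProfile}.
#' @return \code{nPoints}: integer number of observations.
#'   \code{mergeHeights}: numeric vector of merge heights.
#'   \code{kHat}: integer cluster-count estimate.
#'   \code{methodName}: character method identifier.
#'   \code{diagnostics}: named list of method diagnostics.
#'   \code{gapCurve}: data.frame with columns \code{k}, \code{logW},
#'   \code{expectedLogW}, \code{gap}, \code{se}.
#' @examples
#' ms <- computeLinkage(cbind(c(0, 1, 10)))
#' nPoints(ms)
#' mergeHeights(ms)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("mergeHeights", function(object) standardGeneric("mergeHeights"))

#' @rdname accessors
#' @export
setGeneric("kHat", function(object) standardGeneric("kHat"))

#' @rdname accessors
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))

#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname accessors
#' @export
setGeneric("gapCurve", function(object) standardGeneric("gapCurve"))

#' @rdname accessors
setMethod("nPoints", "MergeSequence", function(object) object@nPoints)

#' @rdname accessors
setMethod("mergeHeights", "MergeSequence", function(object) object@heights)

#' @rdname accessors
setMethod("kHat", "ClusterCountEstimate", function(object) object@kHat)

#' @rdname accessors
setMethod("methodName", "ClusterCountEstimate", function(object) object@method)

#' @rdname accessors
setMethod("diagnostics", "ClusterCountEstimate",
          function(object) object@diagnostics)

#' @rdname accessors
setMethod("gapCurve", "GapProfile", function(object) {
  data.frame(k = seq_len(object@kMax), logW = object@logW,
             expectedLogW = object@expectedLogW, gap = object@gap,
             se = object@se)
})
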