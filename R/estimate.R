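#' Estimate the number of clusters in one call
#'
#' Convenience dispatcher: computes the average-linkage hierarchy of the
#' data and applies the chosen cutoff rule. The height-based rules
#' (\code{"elbow"}, \code{"maxdiff"}, \code{"mode"}) accept precomputed
#' distances; the gap statistic needs the raw matrix because its reference
#' datasets are drawn over the observed feature ranges.
#'
#' @param x numeric matrix (observations in rows), or a
#'   \code{\link[stats]{dist}} for the height-based methods.
#' @param method one of \code{"elbow"}, \code{"maxdiff"}, \code{"mode"},
#'   \code{"gap"}.
#' @param alpha mode-method threshold multiplier (see
#'   \code{\link{modeEstimate}}).
#' @param kMax,nReference,seed gap-statistic parameters (see
#'   \code{\link{gapProfile}}).
#' @param linkage linkage criterion; default \code{"average"}.
#' @return a \linkS4class{ClusterCountEstimate}.
#' @examples
#' x <- generateClusters(kTrue = 2, pointsPerCluster = 30, seed = 1)
#' kHat(estimateK(x, "maxdiff"))
#' @export
estimateK <- function(x, method = c("elbow", "maxdiff", "mode", "gap"),
                      alpha = 3, kMax = 10, nReference = 50, seed = NULL,
                      linkage = "average") {
  method <- match.arg(method)
  if (method == "gap") {
    if (inherits(x, "dist"))
      stop("the gap statistic needs the data matrix, not precomputed distances")
    return(gapEstimate(gapProfile(x, kMax = kMax, nReference = nReference,
                                  seed = seed, linkage = linkage)))
  }
  ms <- if (is(x, "MergeSequence")) x else computeLinkage(x, linkage = linkage)
  .estimateFromMerges(ms, method, alpha = alpha)
}

# Height-based estimators from an existing merge sequence (fast path used
# by the resampling wrappers and the simulation harness).
.estimateFromMerges <- function(ms, method, alpha = 3) {
  switch(method,
         elbow   = elbowEstimate(ms),
         maxdiff = maxDiffEstimate(ms),
         mode    = modeEstimate(ms, alpha = alpha),
         stop(sprintf("unknown height-based method '%s'", method)))
}
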