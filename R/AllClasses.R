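#' @import methods
NULL

#' MergeSequence: an agglomerative clustering as an ordered merge sequence
#'
#' Container for the result of an agglomerative hierarchical clustering of
#' \code{N} observations: the \code{N - 1} merge heights in merge order
#' together with the merge tree, which is sufficient to reconstruct the
#' cluster membership at any cut. The merge matrix follows the
#' \code{\link[stats]{hclust}} convention: row \code{i} gives the two children
#' of merge \code{i}, negative entries are leaves, positive entries earlier
#' merges.
#'
#' Average linkage on a metric is monotone, so the heights are non-decreasing;
#' the validity method enforces this (tiny numerical inversions below 1e-9 are
#' clamped at construction time by \code{\link{computeLinkage}}).
#'
#' @slot nPoints integer, the number of observations \code{N} (\code{N >= 2}).
#' @slot heights numeric vector of length \code{N - 1}, non-decreasing, all
#'   \code{>= 0}.
#' @slot merge integer matrix \code{(N - 1) x 2} in \code{hclust} convention.
#' @slot order integer permutation of \code{1:N} for dendrogram plotting.
#' @slot labels character vector of observation labels, or \code{character(0)}.
#' @slot linkage character, the linkage criterion used (default "average").
#' @slot metric character, the distance metric used (default "euclidean").
#'
#' @seealso \code{\link{computeLinkage}}, \code{\link{cutToK}},
#'   \code{\link{cutAtHeight}}
#' @exportClass MergeSequence
setClass("MergeSequence",
  representation(
    nPoints = "integer",
    heights = "numeric",
    merge   = "matrix",
    order   = "integer",
    labels  = "character",
    linkage = "character",
    metric  = "character"
  )
)

setValidity("MergeSequence", function(object) {
  msg <- character(0)
  n <- object@nPoints
  m <- length(object@heights)
  if (length(n) != 1L || is.na(n) || n < 2L)
    msg <- c(msg, "nPoints must be a single integer >= 2")
  else {
    if (m != n - 1L)
      msg <- c(msg, sprintf("expected %d merge heights, got %d", n - 1L, m))
    if (!all(is.finite(object@heights)) || any(object@heights < 0))
      msg <- c(msg, "heights must be finite and >= 0")
    if (m > 1L && any(diff(object@heights) < 0))
      msg <- c(msg, "heights must be non-decreasing (monotone linkage)")
    if (!is.numeric(object@merge) || nrow(object@merge) != m ||
        ncol(object@merge) != 2L)
      msg <- c(msg, "merge must be an (N-1) x 2 matrix")
    if (length(object@labels) && length(object@labels) != n)
      msg <- c(msg, "labels must be empty or length nPoints")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterCountEstimate: an estimated number of clusters with diagnostics
#'
#' The value returned by every estimator in the package: the estimated number
#' of clusters \code{kHat}, the method that produced it, and a list of
#' method-specific diagnostics (argmax index and criterion curve for the
#' height-based methods, threshold for the mode method, the gap curve and a
#' no-elbow flag for the gap statistic, the replicate histogram for the
#' resampling wrappers).
#'
#' @slot kHat integer estimate of the number of clusters, \code{>= 1}.
#' @slot method character method identifier, e.g. \code{"elbow"},
#'   \code{"maxdiff"}, \code{"mode"}, \code{"gap"}, or a resampling-wrapped
#'   variant such as \code{"maxdiff+mixing"}.
#' @slot diagnostics named list of method-specific scalars and vectors.
#'
#' @seealso \code{\link{elbowEstimate}}, \code{\link{maxDiffEstimate}},
#'   \code{\link{modeEstimate}}, \code{\link{gapEstimate}},
#'   \code{\link{mixedEstimate}}, \code{\link{loocvEstimate}}
#' @exportClass ClusterCountEstimate
setClass("ClusterCountEstimate",
  representation(
    kHat        = "integer",
    method      = "character",
    diagnostics = "list"
  )
)

setValidity("ClusterCountEstimate", function(object) {
  msg <- character(0)
  if (length(object@kHat) != 1L || is.na(object@kHat) || object@kHat < 1L)
    msg <- c(msg, "kHat must be a single integer >= 1")
  if (length(object@method) != 1L || !nzchar(object@method))
    msg <- c(msg, "method must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' GapProfile: per-k gap statistic curves
#'
#' Holds, for each candidate cluster number \code{k = 1, ..., kMax}, the
#' observed log within-cluster dispersion \code{log(W_k)}, its expectation
#' under the uniform reference distribution estimated from \code{B} reference
#' datasets, the gap \code{Gap(k) = E*[log(W_k)] - log(W_k)}, and the
#' simulation standard error \code{s_k = sd * sqrt(1 + 1/B)}.
#'
#' @slot logW numeric vector of observed \code{log(W_k)}.
#' @slot expectedLogW numeric vector of reference means \code{E*[log(W_k)]}.
#' @slot gap numeric vector, \code{expectedLogW - logW}.
#' @slot se numeric vector of standard errors \code{s_k}, all \code{>= 0}.
#' @slot kMax integer, number of candidate cluster counts profiled.
#' @slot nReference integer, number of reference datasets \code{B}.
#' @slot seed integer seed used for the reference draws, or \code{NA}.
#'
#' @seealso \code{\link{gapProfile}}, \code{\link{gapEstimate}}
#' @exportClass GapProfile
setClass("GapProfile",
  representation(
    logW         = "numeric",
    expectedLogW = "numeric",
    gap          = "numeric",
    se           = "numeric",
    kMax         = "integer",
    nReference   = "integer",
    seed         = "integer"
  )
)

setValidity("GapProfile", function(object) {
  msg <- character(0)
  k <- object@kMax
  lens <- c(length(object@logW), length(object@expectedLogW),
            length(object@gap), length(object@se))
  if (any(lens != k))
    msg <- c(msg, "logW, expectedLogW, gap and se must all have length kMax")
  if (any(object@se < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(object@nReference) != 1L || object@nReference < 2L)
    msg <- c(msg, "nReference must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MergeSequence", function(object) {
  cat(sprintf("MergeSequence of %d observations (%s linkage, %s distance)\n",
              object@nPoints, object@linkage, object@metric))
  h <- object@heights
  cat(sprintf("  %d merges, heights in [%.4g, %.4g]\n",
              length(h), min(h), max(h)))
})

setMethod("show", "ClusterCountEstimate", function(object) {
  cat(sprintf("ClusterCountEstimate: kHat = %d (method: %s)\n",
              object@kHat, object@method))
  d <- object@diagnostics
  if (isTRUE(d$noElbow))
    cat("  note: selection rule never fired below kMax; kHat = kMax\n")
  if (!is.null(d$nFailed) && d$nFailed > 0L)
    cat(sprintf("  note: %d of %d replicates failed and were skipped\n",
                d$nFailed, d$nReplicates))
})

setMethod("show", "GapProfile", function(object) {
  cat(sprintf("GapProfile over k = 1..%d (B = %d reference sets)\n",
              object@kMax, object@nReference))
  print(data.frame(k = seq_len(object@kMax),
                   logW = round(object@logW, 4),
                   expectedLogW = round(object@expectedLogW, 4),
                   gap = round(object@gap, 4),
                   se = round(object@se, 4)), row.names = FALSE)
})
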