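#' Agglomerative average-linkage clustering as a merge sequence
#'
#' Runs agglomerative hierarchical clustering (average linkage, Euclidean
#' distance by default) on a numeric observations-by-features matrix and
#' returns the ordered merge sequence. All cutoff estimators in this package
#' operate on the \code{N - 1} merge heights \eqn{d_1 \le \dots \le d_{N-1}}
#' of this sequence.
#'
#' Average linkage defines the distance between two clusters as the mean of
#' all between-cluster pairwise point distances; it is a monotone criterion,
#' so merge heights are non-decreasing. Numerical inversions smaller than
#' 1e-9 are clamped; larger inversions (possible only for non-monotone
#' linkage choices such as \code{"median"} or \code{"centroid"}) raise an
#' error, because the height-based estimators are not defined on a
#' non-monotone sequence.
#'
#' @param x numeric matrix or data.frame with observations in rows and
#'   features in columns (\code{N >= 2}, all entries finite), or a
#'   \code{\link[stats]{dist}} object of precomputed distances.
#' @param linkage linkage criterion passed to \code{\link[stats]{hclust}};
#'   default \code{"average"}. Only monotone linkages are supported.
#' @param metric distance metric passed to \code{\link[stats]{dist}} when
#'   \code{x} is a matrix; default \code{"euclidean"}.
#' @return a \linkS4class{MergeSequence}.
#' @examples
#' ms <- computeLinkage(cbind(c(0, 1, 10)))
#' mergeHeights(ms)  # 1.0, then mean(c(10, 9)) = 9.5
#' @seealso \code{\link{cutToK}}, \code{\link{cutAtHeight}},
#'   \code{\link{mergeTable}}
#' @export
computeLinkage <- function(x, linkage = "average", metric = "euclidean") {
  if (inherits(x, "dist")) {
    if (!all(is.finite(x)))
      stop("distance object contains non-finite values")
    n <- attr(x, "Size")
    if (is.null(n) || n < 2L)
      stop("at least 2 observations are required")
    d <- x
    labs <- attr(x, "Labels")
  } else {
    x <- as.matrix(x)
    if (!is.numeric(x))
      stop("input must be a numeric matrix")
    if (nrow(x) < 2L)
      stop("at least 2 observations (rows) are required")
    if (ncol(x) < 1L)
      stop("at least 1 feature (column) is required")
    if (!all(is.finite(x))) {
      bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]))
    }
    d <- stats::dist(x, method = metric)
    labs <- rownames(x)
  }
  hc <- stats::hclust(d, method = linkage)
  h <- hc$height
  if (length(h) > 1L) {
    dh <- diff(h)
    if (any(dh < 0)) {
      if (min(dh) < -1e-9)
        stop(sprintf(
          "merge heights are not non-decreasing (inversion of %.3g); %s",
          -min(dh), "use a monotone linkage such as 'average'"))
      h <- cummax(h)  # clamp numerical noise
    }
  }
  new("MergeSequence",
      nPoints = length(hc$order),
      heights = h,
      merge   = hc$merge,
      order   = as.integer(hc$order),
      labels  = if (is.null(labs)) character(0) else as.character(labs),
      linkage = linkage,
      metric  = if (inherits(x, "dist")) "precomputed" else metric)
}

# Rebuild a stats::hclust object so cutree() and plotting can be reused.
asHclust <- function(ms) {
  stopifnot(is(ms, "MergeSequence"))
  structure(
    list(merge = ms@merge, height = ms@heights, order = ms@order,
         labels = if (length(ms@labels)) ms@labels else NULL,
         method = ms@linkage, call = NULL,
         dist.method = ms@metric),
    class = "hclust")
}

#' @describeIn computeLinkage coerce a MergeSequence back to a
#'   \code{\link[stats]{hclust}} object (e.g. for \code{plot()}).
#' @param ... ignored.
#' @exportS3Method stats::as.hclust
as.hclust.MergeSequence <- function(x, ...) asHclust(x)

#' Cut a merge sequence into k clusters
#'
#' Recovers the partition into \code{k} clusters by undoing the last
#' \code{k - 1} merges of the sequence.
#'
#' @param ms a \linkS4class{MergeSequence}.
#' @param k integer number of clusters, \code{1 <= k <= N}.
#' @return integer vector of cluster labels in \code{1..k}, one per
#'   observation, numbered in order of first appearance (the
#'   \code{\link[stats]{cutree}} convention); named by the observation labels
#'   when present.
#' @examples
#' ms <- computeLinkage(cbind(c(0, 1, 10)))
#' cutToK(ms, 2)  # {0, 1} together, {10} alone
#' @export
cutToK <- function(ms, k) {
  stopifnot(is(ms, "MergeSequence"))
  n <- ms@nPoints
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1L || k > n)
    stop(sprintf("k must be a single integer in [1, %d]", n))
  labs <- stats::cutree(asHclust(ms), k = as.integer(k))
  if (!length(ms@labels)) labs <- unname(labs)
  labs
}

#' Cut a merge sequence at a height threshold
#'
#' Applies exactly the merges with height \code{<= h}; the resulting number
#' of clusters is \code{N} minus the number of merges applied. This is the
#' cut used by the mode estimator, whose decision rule is a height threshold
#' rather than a cluster count.
#'
#' @param ms a \linkS4class{MergeSequence}.
#' @param h non-negative height threshold.
#' @return integer vector of cluster labels, as in \code{\link{cutToK}}.
#' @examples
#' ms <- computeLinkage(cbind(c(0, 1, 10)))
#' max(cutAtHeight(ms, 5))  # 2 clusters: only the height-1 merge applies
#' @export
cutAtHeight <- function(ms, h) {
  stopifnot(is(ms, "MergeSequence"))
  if (length(h) != 1L || is.na(h) || h < 0)
    stop("h must be a single non-negative number")
  k <- ms@nPoints - sum(ms@heights <= h)
  cutToK(ms, max(k, 1L))
}

#' Export a merge sequence as a linkage table
#'
#' Flattens the merge tree into the common \code{(N - 1) x 4} linkage-matrix
#' layout: one row per merge with the ids of the two children, the merge
#' height, and the size of the newly formed cluster. Leaves carry ids
#' \code{1..N}; merge \code{i} carries id \code{N + i}.
#'
#' @param ms a \linkS4class{MergeSequence}.
#' @return data.frame with columns \code{child_a}, \code{child_b},
#'   \code{height}, \code{size}.
#' @export
mergeTable <- function(ms) {
  stopifnot(is(ms, "MergeSequence"))
  n <- ms@nPoints
  m <- n - 1L
  id <- function(v) ifelse(v < 0, -v, n + v)
  sizes <- integer(m)
  csize <- function(v) ifelse(v < 0, 1L, sizes[v])
  for (i in seq_len(m))
    sizes[i] <- csize(ms@merge[i, 1L]) + csize(ms@merge[i, 2L])
  data.frame(child_a = id(ms@merge[, 1L]), child_b = id(ms@merge[, 2L]),
             height = ms@heights, size = sizes)
}
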