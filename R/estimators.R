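#' Elbow (acceleration) estimate of the number of clusters
#'
#' Selects the merge at which the growth of the merge heights accelerates
#' the most: with \code{m = N - 1} heights \eqn{d_1 \le \dots \le d_m}, the
#' acceleration at merge \eqn{i} is the second difference
#' \eqn{d_i - 2 d_{i-1} + d_{i-2}} for \eqn{i = 3, \dots, m}, and the
#' estimate is \eqn{\hat{k} = m + 2 - i^*} where \eqn{i^*} is the first
#' index attaining the maximum. \eqn{m + 2 - i} is the number of clusters
#' present just before merge \eqn{i} is applied.
#'
#' By construction \eqn{\hat{k} \ge 2}: like all purely height-based rules
#' that pick an interior merge, this estimator cannot return the
#' single-cluster answer.
#'
#' @param ms a \linkS4class{MergeSequence} with at least 3 merges
#'   (\code{N >= 4}).
#' @return a \linkS4class{ClusterCountEstimate} with diagnostics
#'   \code{argmaxIndex} (\eqn{i^*}), \code{acceleration} (the second
#'   differences, named by merge index) and \code{maxAcceleration}.
#' @references The acceleration view of dendrogram elbows is the common
#'   variant of the elbow heuristic for hierarchical clusterings.
#' @seealso \code{\link{maxDiffEstimate}}, \code{\link{modeEstimate}},
#'   \code{\link{gapEstimate}}
#' @export
elbowEstimate <- function(ms) {
  stopifnot(is(ms, "MergeSequence"))
  d <- ms@heights
  m <- length(d)
  if (m < 3L)
    stop("insufficient merges: the elbow estimator needs at least 3 (N >= 4)")
  i <- 3:m
  acc <- d[i] - 2 * d[i - 1L] + d[i - 2L]
  iStar <- i[which.max(acc)]  # which.max: first maximum, i.e. smallest i
  newEstimate(m + 2L - iStar, "elbow",
              list(argmaxIndex = iStar,
                   acceleration = stats::setNames(acc, i),
                   maxAcceleration = max(acc)))
}

#' Maximum-difference estimate of the number of clusters
#'
#' Selects the merge preceded by the largest jump in merge height: the
#' estimate is \eqn{\hat{k} = m + 2 - i^*} with
#' \eqn{i^* = \arg\max_{i \in [2, m]} (d_i - d_{i-1})}, ties going to the
#' smallest index. Equivalently, the dendrogram is cut inside the widest
#' height gap between consecutive merges. Like the elbow rule it never
#' returns 1 cluster, though it handles singleton clusters.
#'
#' @param ms a \linkS4class{MergeSequence} with at least 2 merges
#'   (\code{N >= 3}).
#' @return a \linkS4class{ClusterCountEstimate} with diagnostics
#'   \code{argmaxIndex}, \code{differences} (consecutive height differences,
#'   named by merge index) and \code{maxDifference}.
#' @export
maxDiffEstimate <- function(ms) {
  stopifnot(is(ms, "MergeSequence"))
  d <- ms@heights
  m <- length(d)
  if (m < 2L)
    stop("insufficient merges: the maximum-difference estimator needs at least 2 (N >= 3)")
  dif <- d[-1L] - d[-m]
  iStar <- which.max(dif) + 1L
  newEstimate(m + 2L - iStar, "maxdiff",
              list(argmaxIndex = iStar,
                   differences = stats::setNames(dif, 2:m),
                   maxDifference = max(dif)))
}

#' Mode (modal jump size) estimate of the number of clusters
#'
#' Treats the empirical distribution of merge heights as the signal: the
#' most common jump size is unlikely to be a good cutoff, so the dendrogram
#' is cut at the height threshold \eqn{\hat{D} + \alpha \sigma_D}, where
#' \eqn{\hat{D}} is the modal merge height and \eqn{\sigma_D} the sample
#' standard deviation of the heights. The estimate is the number of clusters
#' remaining at that cut (\code{\link{cutAtHeight}}), which can legitimately
#' be 1 when the threshold exceeds the last merge.
#'
#' The mode of a continuous sample is estimated by a histogram with
#' \eqn{\lceil\sqrt{m}\rceil} equal-width bins spanning the height range;
#' \eqn{\hat{D}} is the midpoint of the fullest bin (ties to the lowest
#' bin). When all heights are equal the mode is that height and
#' \eqn{\sigma_D = 0}.
#'
#' @param ms a \linkS4class{MergeSequence} with at least 2 merges.
#' @param alpha non-negative multiplier on \eqn{\sigma_D}; default 3. The
#'   default is deliberately untuned: tuning would need labelled training
#'   data, which defeats the point of an automated cutoff.
#' @return a \linkS4class{ClusterCountEstimate} with diagnostics
#'   \code{modalHeight}, \code{sdHeights}, \code{threshold} and
#'   \code{nBins}.
#' @export
modeEstimate <- function(ms, alpha = 3) {
  stopifnot(is(ms, "MergeSequence"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single finite number >= 0")
  d <- ms@heights
  m <- length(d)
  if (m < 2L)
    stop("insufficient merges: the mode estimator needs at least 2 (N >= 3)")
  nBins <- as.integer(ceiling(sqrt(m)))
  lo <- min(d); hi <- max(d)
  if (hi == lo) {
    dHat <- lo
  } else {
    w <- (hi - lo) / nBins
    bin <- pmin(floor((d - lo) / w) + 1L, nBins)
    counts <- tabulate(bin, nBins)
    modal <- which.max(counts)  # ties: lowest bin
    dHat <- lo + (modal - 0.5) * w
  }
  sdD <- stats::sd(d)
  thr <- dHat + alpha * sdD
  k <- ms@nPoints - sum(d <= thr)
  newEstimate(max(k, 1L), "mode",
              list(modalHeight = dHat, sdHeights = sdD, threshold = thr,
                   nBins = nBins))
}

#' Within-cluster dispersion W_k
#'
#' The size-normalised sum of within-cluster pairwise distances,
#' \deqn{W_k = \sum_{r=1}^{k} \frac{1}{2 n_r} \sum_{i, i' \in C_r} d_{i i'},}
#' with the inner sum over ordered pairs (each unordered pair counted twice)
#' and \eqn{d} the Euclidean distance. This is the dispersion the gap
#' statistic compares against its reference expectation.
#'
#' @param x numeric matrix (observations in rows), a
#'   \code{\link[stats]{dist}}, or a full symmetric distance matrix.
#' @param assignment integer cluster labels, one per observation; every
#'   cluster must be non-empty.
#' @return a single non-negative number.
#' @examples
#' withinClusterDispersion(cbind(c(0, 1, 2)), c(1, 1, 1))  # 4/3
#' @export
withinClusterDispersion <- function(x, assignment) {
  Dm <- if (inherits(x, "dist")) as.matrix(x)
        else if (is.matrix(x) && nrow(x) == ncol(x) &&
                 isTRUE(all.equal(unname(x), unname(t(x)))) &&
                 all(diag(x) == 0)) x
        else as.matrix(stats::dist(x))
  n <- nrow(Dm)
  if (length(assignment) != n)
    stop("assignment length must match the number of observations")
  .dispersionFromDistmat(Dm, assignment)
}

# Core W_k computation on a full distance matrix; assignment validated.
.dispersionFromDistmat <- function(Dm, assignment) {
  sizes <- tabulate(assignment)
  if (any(sizes == 0L))
    stop("empty cluster in assignment")
  # sum over ordered within-cluster pairs for every cluster at once
  blockSums <- rowsum(t(rowsum(Dm, assignment)), assignment)
  sum(diag(blockSums) / (2 * sizes))
}
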