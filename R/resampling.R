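#' Mode of a set of cluster-count estimates
#'
#' The consensus value used by the resampling wrappers: the most frequent
#' count, with ties broken towards the smallest value (the conservative
#' choice).
#'
#' @param counts non-empty integer vector of per-replicate estimates;
#'   \code{NA}s (failed replicates) are dropped.
#' @return a single integer.
#' @examples
#' modeOfCounts(c(3, 3, 3, 4))  # 3
#' modeOfCounts(c(2, 2, 3, 3))  # tie -> 2
#' @export
modeOfCounts <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts))
    stop("no estimates to aggregate")
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])  # names sorted ascending; ties -> smallest
}

#' Half-sample mixing estimate of the number of clusters
#'
#' Runs a base estimator on \code{L} random subsamples of \code{M}
#' observations drawn without replacement, and reports the mode of the
#' \code{L} per-replicate estimates. Subsampling averages out the influence
#' of outlying points on the merge heights; the default \code{M = N/2},
#' \code{L = 100} mirrors half-sample cross-validation.
#'
#' Replicates on which the base estimator fails (e.g. too few merges) are
#' skipped and counted; more than 50\% failures is an error.
#'
#' @param x numeric matrix (observations in rows), or a
#'   \code{\link[stats]{dist}} for the height-based methods.
#' @param method base estimator: \code{"elbow"}, \code{"maxdiff"},
#'   \code{"mode"} or \code{"gap"} (the latter is supported but expensive).
#' @param M subsample size; default \code{floor(N / 2)}.
#' @param L number of replicates; default 100.
#' @param seed integer seed for the subsample draws, or \code{NULL}.
#' @param alpha,kMax,nReference base-estimator parameters, inherited
#'   unchanged by every replicate.
#' @return a \linkS4class{ClusterCountEstimate} with method
#'   \code{"<method>+mixing"} and diagnostics \code{replicates} (the
#'   per-replicate estimates, \code{NA} where failed), \code{histogram},
#'   \code{nFailed}, \code{nReplicates}, \code{M}, \code{L}, \code{seed}.
#' @seealso \code{\link{loocvEstimate}}, \code{\link{modeOfCounts}}
#' @export
mixedEstimate <- function(x, method = c("elbow", "maxdiff", "mode", "gap"),
                          M = NULL, L = 100, seed = NULL, alpha = 3,
                          kMax = 10, nReference = 50) {
  method <- match.arg(method)
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(as.matrix(x))
  if (is.null(M)) M <- floor(n / 2)
  M <- as.integer(M); L <- as.integer(L)
  if (M < 2L || M > n)
    stop(sprintf("M must be in [2, %d]", n))
  if (L < 1L)
    stop("L must be >= 1")
  useDist <- method != "gap"
  Dm <- if (useDist) as.matrix(if (inherits(x, "dist")) x else stats::dist(x))
  xm <- if (!useDist) as.matrix(x)
  ks <- withSeed(seed, {
    vapply(seq_len(L), function(j) {
      idx <- sample.int(n, M)
      tryCatch({
        if (useDist) {
          ms <- computeLinkage(stats::as.dist(Dm[idx, idx]))
          kHat(.estimateFromMerges(ms, method, alpha = alpha))
        } else {
          kHat(estimateK(xm[idx, , drop = FALSE], method = "gap",
                         kMax = kMax, nReference = nReference))
        }
      }, error = function(e) NA_integer_)
    }, integer(1))
  })
  .aggregateReplicates(ks, paste0(method, "+mixing"),
                       list(M = M, L = L,
                            seed = if (is.null(seed)) NA_integer_
                                   else as.integer(seed)))
}

#' Leave-one-out consensus estimate of the number of clusters
#'
#' The limiting case of the mixing scheme: each observation is removed once,
#' the base estimator is run on the remaining \code{N - 1} observations, and
#' the mode of the \code{N} estimates is reported.
#'
#' @inheritParams mixedEstimate
#' @param seed seed used only when the base estimator itself is stochastic
#'   (the gap statistic); the leave-one-out subsets are deterministic.
#' @return a \linkS4class{ClusterCountEstimate} with method
#'   \code{"<method>+loocv"} and the same diagnostics as
#'   \code{\link{mixedEstimate}} (with \code{M = N - 1}, \code{L = N}).
#' @export
loocvEstimate <- function(x, method = c("elbow", "maxdiff", "mode", "gap"),
                          seed = NULL, alpha = 3, kMax = 10,
                          nReference = 50) {
  method <- match.arg(method)
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(as.matrix(x))
  if (n < 3L)
    stop("leave-one-out needs at least 3 observations")
  useDist <- method != "gap"
  Dm <- if (useDist) as.matrix(if (inherits(x, "dist")) x else stats::dist(x))
  xm <- if (!useDist) as.matrix(x)
  ks <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      idx <- setdiff(seq_len(n), i)
      tryCatch({
        if (useDist) {
          ms <- computeLinkage(stats::as.dist(Dm[idx, idx]))
          kHat(.estimateFromMerges(ms, method, alpha = alpha))
        } else {
          kHat(estimateK(xm[idx, , drop = FALSE], method = "gap",
                         kMax = kMax, nReference = nReference))
        }
      }, error = function(e) NA_integer_)
    }, integer(1))
  })
  .aggregateReplicates(ks, paste0(method, "+loocv"),
                       list(M = n - 1L, L = n,
                            seed = if (is.null(seed)) NA_integer_
                                   else as.integer(seed)))
}

.aggregateReplicates <- function(ks, method, extra) {
  nFail <- sum(is.na(ks))
  L <- length(ks)
  if (nFail > L / 2)
    stop(sprintf("estimator failed on %d of %d replicates (more than half)",
                 nFail, L))
  newEstimate(modeOfCounts(ks), method,
              c(list(replicates = ks, histogram = table(ks),
                     nFailed = nFail, nReplicates = L), extra))
}
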