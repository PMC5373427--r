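#' Generate Gaussian clusters on a square arrangement
#'
#' Draws \code{kTrue} clusters of \code{pointsPerCluster} points each from
#' multivariate normal distributions with spherical covariance
#' \eqn{scale_r I_p}. The default centers place up to four clusters on the
#' corners of a square of side \code{separation} in 2-D, taken in the fixed
#' order \eqn{(-m/2, -m/2)}, \eqn{(m/2, m/2)}, \eqn{(-m/2, m/2)},
#' \eqn{(m/2, -m/2)}; with the default \code{separation = 6} these are
#' \eqn{(\pm 3, \pm 3)}. For \code{kTrue < 4} the first \code{kTrue} centers
#' are used, so a single cluster sits at \eqn{(-3, -3)}.
#'
#' @param kTrue number of clusters (1-4 under the default centers; more
#'   with explicit \code{centers}).
#' @param pointsPerCluster points drawn per cluster; default 100.
#' @param dim data dimension \code{p}; default 2. Dimensions other than 2
#'   require \code{kTrue <= 2} (the diagonal corners generalise) or explicit
#'   \code{centers}.
#' @param separation side length \code{m} of the center square; default 6.
#' @param covScales numeric vector of per-cluster covariance scales
#'   (covariance \eqn{scale_r I_p}); default all 1. The heterogeneous
#'   setting uses \code{c(1, 1, 2, 0.5)}.
#' @param centers optional \code{kTrue x dim} matrix of cluster centers
#'   overriding the square arrangement.
#' @param seed integer seed, or \code{NULL} to consume the caller's stream.
#' @return numeric matrix of \code{kTrue * pointsPerCluster} rows and
#'   \code{dim} columns, rows grouped by cluster, with the generating labels
#'   in \code{attr(, "trueCluster")}.
#' @examples
#' x <- generateClusters(kTrue = 4, seed = 1)
#' dim(x)  # 400 x 2
#' @export
generateClusters <- function(kTrue, pointsPerCluster = 100, dim = 2,
                             separation = 6, covScales = NULL,
                             centers = NULL, seed = NULL) {
  kTrue <- as.integer(kTrue)
  if (kTrue < 1L)
    stop("kTrue must be >= 1")
  if (is.null(centers)) {
    if (dim == 2L) {
      corners <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))
    } else {
      corners <- rbind(rep(-1, dim), rep(1, dim))
    }
    if (kTrue > nrow(corners))
      stop(sprintf(
        "kTrue = %d exceeds the %d default centers; supply centers=",
        kTrue, nrow(corners)))
    centers <- corners[seq_len(kTrue), , drop = FALSE] * separation / 2
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != kTrue || ncol(centers) != dim)
      stop("centers must be a kTrue x dim matrix")
  }
  if (is.null(covScales)) covScales <- rep(1, kTrue)
  if (length(covScales) == 1L) covScales <- rep(covScales, kTrue)
  if (length(covScales) != kTrue || any(covScales <= 0))
    stop("covScales must be kTrue positive values")
  n <- as.integer(pointsPerCluster)
  if (n < 1L)
    stop("pointsPerCluster must be >= 1")
  x <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(kTrue), function(r) {
      matrix(stats::rnorm(n * dim, sd = sqrt(covScales[r])), n, dim) +
        rep(centers[r, ], each = n)
    }))
  })
  attr(x, "trueCluster") <- rep(seq_len(kTrue), each = n)
  x
}

#' Success rate of a set of cluster-count estimates
#'
#' The fraction of estimates equal to the true cluster number.
#'
#' @param estimates non-empty integer vector of estimates; \code{NA}s
#'   (failed runs) are excluded from the denominator.
#' @param kTrue true number of clusters.
#' @return a number in \code{[0, 1]}.
#' @examples
#' successRate(c(4, 4, 3, 4), 4)  # 0.75
#' @export
successRate <- function(estimates, kTrue) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates))
    stop("no estimates")
  mean(estimates == kTrue)
}

#' Conditional error size of a set of cluster-count estimates
#'
#' The mean absolute deviation \eqn{|k - \hat{k}|} over the incorrect
#' estimates only; defined as 0 when every estimate is correct (so a
#' success rate of 1 always pairs with an error size of 0).
#'
#' @inheritParams successRate
#' @return a non-negative number.
#' @examples
#' errorSize(c(4, 4, 3, 6), 4)  # mean(c(1, 2)) = 1.5
#' @export
errorSize <- function(estimates, kTrue) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates))
    stop("no estimates")
  wrong <- estimates[estimates != kTrue]
  if (!length(wrong)) 0 else mean(abs(kTrue - wrong))
}

#' Monte-Carlo evaluation of the cutoff estimators
#'
#' Repeats: generate a dataset from the Gaussian-cluster scenario, apply
#' every configured estimator (optionally wrapped in half-sample mixing or
#' leave-one-out consensus) to the same dataset, and record the estimates.
#' Methods are paired within a run -- they see identical data, and under
#' resampling the height-based methods also share the same subsample draws.
#' One master seed spawns independent per-run substreams, so results are
#' reproducible and runs are independent.
#'
#' @param kTrue true number of clusters of the scenario.
#' @param methods character vector from \code{"elbow"}, \code{"maxdiff"},
#'   \code{"mode"}, \code{"gap"}.
#' @param nRuns number of simulated datasets; default 200.
#' @param pointsPerCluster,separation,covScales,dim scenario parameters
#'   passed to \code{\link{generateClusters}}.
#' @param resampling \code{"none"} (default), \code{"mixing"} or
#'   \code{"loocv"}.
#' @param M,L mixing parameters (see \code{\link{mixedEstimate}}).
#' @param alpha,kMax,nReference estimator parameters.
#' @param seed master seed; default \code{NULL}.
#' @return data.frame with one row per method: \code{method}, \code{k_true},
#'   \code{separation}, \code{n_runs}, \code{mean_k_hat},
#'   \code{success_rate}, \code{error_size}, \code{n_wrong},
#'   \code{n_failed}, \code{seed}.
#' @seealso \code{\link{separationSweep}}
#' @export
runExperiment <- function(kTrue, methods = c("elbow", "maxdiff", "mode"),
                          nRuns = 200, pointsPerCluster = 100,
                          separation = 6, covScales = NULL, dim = 2,
                          resampling = c("none", "mixing", "loocv"),
                          M = NULL, L = 100, alpha = 3, kMax = 10,
                          nReference = 50, seed = NULL) {
  resampling <- match.arg(resampling)
  methods <- match.arg(methods, c("elbow", "maxdiff", "mode", "gap"),
                       several.ok = TRUE)
  if (nRuns < 1L)
    stop("nRuns must be >= 1")
  runSeeds <- deriveSeeds(seed, nRuns)
  ks <- matrix(NA_integer_, nrow = nRuns, ncol = length(methods),
               dimnames = list(NULL, methods))
  for (j in seq_len(nRuns)) {
    subSeeds <- if (is.na(runSeeds[j])) c(NA_integer_, NA_integer_)
                else deriveSeeds(runSeeds[j], 2L)
    x <- generateClusters(kTrue, pointsPerCluster = pointsPerCluster,
                          dim = dim, separation = separation,
                          covScales = covScales, seed = subSeeds[1L])
    ks[j, ] <- .runOnce(x, methods, resampling, M = M, L = L, alpha = alpha,
                        kMax = kMax, nReference = nReference,
                        estSeed = subSeeds[2L])
  }
  res <- do.call(rbind, lapply(methods, function(m) {
    est <- ks[, m]
    ok <- est[!is.na(est)]
    data.frame(method = if (resampling == "none") m
                        else paste0(m, "+", resampling),
               k_true = kTrue, separation = separation, n_runs = nRuns,
               mean_k_hat = mean(ok),
               success_rate = successRate(est, kTrue),
               error_size = errorSize(est, kTrue),
               n_wrong = sum(ok != kTrue), n_failed = sum(is.na(est)),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }))
  rownames(res) <- NULL
  res
}

# Apply each method once to dataset x, honouring the resampling scheme.
# Returns a named integer vector of estimates (NA = failed).
.runOnce <- function(x, methods, resampling, M, L, alpha, kMax, nReference,
                     estSeed) {
  out <- stats::setNames(rep(NA_integer_, length(methods)), methods)
  hMethods <- intersect(methods, c("elbow", "maxdiff", "mode"))
  tryK <- function(expr) tryCatch(expr, error = function(e) NA_integer_)
  if (resampling == "none") {
    if (length(hMethods)) {
      ms <- tryCatch(computeLinkage(x), error = function(e) NULL)
      if (!is.null(ms))
        for (m in hMethods)
          out[m] <- tryK(kHat(.estimateFromMerges(ms, m, alpha = alpha)))
    }
    if ("gap" %in% methods)
      out["gap"] <- tryK(kHat(estimateK(x, "gap", kMax = kMax,
                                        nReference = nReference,
                                        seed = estSeed)))
    return(out)
  }
  # resampling: height-based methods share one replicate loop (and hence
  # the same subsample draws); the gap statistic gets its own wrapper call.
  n <- nrow(x)
  if (length(hMethods)) {
    Dm <- as.matrix(stats::dist(x))
    Mj <- if (resampling == "loocv") n - 1L
          else if (is.null(M)) floor(n / 2) else as.integer(M)
    Lj <- if (resampling == "loocv") n else as.integer(L)
    reps <- withSeed(estSeed, {
      vapply(seq_len(Lj), function(j) {
        idx <- if (resampling == "loocv") setdiff(seq_len(n), j)
               else sample.int(n, Mj)
        ms <- tryCatch(computeLinkage(stats::as.dist(Dm[idx, idx])),
                       error = function(e) NULL)
        vapply(hMethods, function(m) {
          if (is.null(ms)) NA_integer_
          else tryK(kHat(.estimateFromMerges(ms, m, alpha = alpha)))
        }, integer(1))
      }, integer(length(hMethods)))
    })
    reps <- matrix(reps, nrow = length(hMethods),
                   dimnames = list(hMethods, NULL))
    for (m in hMethods) {
      km <- reps[m, ]
      out[m] <- if (sum(is.na(km)) > Lj / 2) NA_integer_
                else modeOfCounts(km)
    }
  }
  if ("gap" %in% methods) {
    out["gap"] <- tryK(
      if (resampling == "loocv")
        kHat(loocvEstimate(x, "gap", seed = estSeed, kMax = kMax,
                           nReference = nReference))
      else
        kHat(mixedEstimate(x, "gap", M = M, L = L, seed = estSeed,
                           kMax = kMax, nReference = nReference)))
  }
  out
}

#' Evaluate estimators across cluster separations
#'
#' Runs \code{\link{runExperiment}} at each separation value and stacks the
#' summaries into one long-format table, suitable for plotting success rate
#' and error size against separation. As the clusters move apart the
#' height-based estimators approach a success rate of 1 and an error size
#' of 0.
#'
#' @param mValues positive separation values (square side lengths).
#' @param ... arguments passed on to \code{\link{runExperiment}}.
#' @param seed master seed; one sub-seed is derived per separation value.
#' @return data.frame as in \code{\link{runExperiment}}, one row per
#'   (separation, method).
#' @export
separationSweep <- function(mValues, ..., seed = NULL) {
  if (!length(mValues) || any(mValues <= 0))
    stop("mValues must be positive")
  seeds <- deriveSeeds(seed, length(mValues))
  res <- do.call(rbind, lapply(seq_along(mValues), function(i) {
    runExperiment(separation = mValues[i], seed = seeds[i], ...)
  }))
  rownames(res) <- NULL
  res
}
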