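#' Gap statistic profile for a hierarchical clustering
#'
#' Computes, for each candidate number of clusters \code{k = 1, ..., kMax},
#' the observed \eqn{\log W_k} of the average-linkage hierarchy cut to
#' \code{k} clusters, and its expectation under a null reference: \code{B}
#' datasets drawn uniformly over the observed range of each feature, each
#' clustered identically. The gap is
#' \deqn{Gap(k) = E^*[\log W_k] - \log W_k,}
#' and the simulation standard error is
#' \eqn{s_k = sd^*(\log W_k)\sqrt{1 + 1/B}}.
#'
#' The uniform (per-feature range) reference is the simple reference
#' construction recommended for unimodal data; a principal-component-aligned
#' reference box is not implemented.
#'
#' @param x numeric matrix, observations in rows (\code{N > kMax}).
#' @param kMax largest cluster number profiled; default 10.
#' @param nReference number of reference datasets \code{B}; default 50.
#' @param seed integer seed making the reference draws reproducible, or
#'   \code{NULL} to consume the caller's RNG stream.
#' @param linkage linkage criterion for the hierarchies; default
#'   \code{"average"}.
#' @return a \linkS4class{GapProfile}.
#' @seealso \code{\link{gapEstimate}}, \code{\link{withinClusterDispersion}}
#' @export
gapProfile <- function(x, kMax = 10, nReference = 50, seed = NULL,
                       linkage = "average") {
  x <- as.matrix(x)
  n <- nrow(x)
  kMax <- as.integer(kMax)
  if (kMax < 1L)
    stop("kMax must be >= 1")
  if (kMax >= n)
    stop(sprintf("kMax (%d) must be smaller than the number of observations (%d)",
                 kMax, n))
  B <- as.integer(nReference)
  if (B < 2L)
    stop("nReference must be >= 2")
  obs <- .logWProfile(x, kMax, linkage)
  rng <- apply(x, 2L, range)
  refLogW <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      xr <- apply(rng, 2L, function(r) stats::runif(n, r[1L], r[2L]))
      .logWProfile(xr, kMax, linkage)
    }, numeric(kMax))
  })
  refLogW <- matrix(refLogW, nrow = kMax)
  eLogW <- rowMeans(refLogW)
  sk <- apply(refLogW, 1L, stats::sd) * sqrt(1 + 1 / B)
  new("GapProfile", logW = obs, expectedLogW = eLogW, gap = eLogW - obs,
      se = sk, kMax = kMax, nReference = B,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# log W_k for k = 1..kMax of one dataset under the given linkage.
.logWProfile <- function(x, kMax, linkage = "average") {
  Dm <- as.matrix(stats::dist(x))
  hc <- stats::hclust(stats::as.dist(Dm), method = linkage)
  cuts <- stats::cutree(hc, k = seq_len(kMax))
  vapply(seq_len(kMax),
         function(k) log(.dispersionFromDistmat(Dm, cuts[, k])),
         numeric(1))
}

#' Gap statistic estimate of the number of clusters
#'
#' Applies the one-standard-error selection rule to a gap profile: the
#' estimate is the smallest \code{k} with
#' \eqn{Gap(k) \ge Gap(k+1) - s_{k+1}}. Unlike the height-based rules, this
#' estimator can return 1 cluster. If no \code{k < kMax} satisfies the rule
#' the profile has no elbow within range; \code{kMax} is returned with the
#' diagnostic flag \code{noElbow} set.
#'
#' @param profile a \linkS4class{GapProfile} of length \code{>= 2}, from
#'   \code{\link{gapProfile}}.
#' @return a \linkS4class{ClusterCountEstimate} with diagnostics \code{gap},
#'   \code{se}, \code{noElbow}, and the profile parameters.
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' kHat(gapEstimate(gapProfile(x, kMax = 5, nReference = 10, seed = 1)))
#' @export
gapEstimate <- function(profile) {
  stopifnot(is(profile, "GapProfile"))
  g <- profile@gap
  s <- profile@se
  if (length(g) < 2L)
    stop("gap profile must cover at least 2 values of k")
  sel <- which(g[-length(g)] >= g[-1L] - s[-1L])
  noElbow <- length(sel) == 0L
  k <- if (noElbow) profile@kMax else sel[1L]
  newEstimate(k, "gap",
              list(gap = g, se = s, noElbow = noElbow,
                   kMax = profile@kMax, nReference = profile@nReference,
                   seed = profile@seed))
}
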