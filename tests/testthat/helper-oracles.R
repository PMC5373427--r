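# Independent oracles used to cross-check the implementation.

# O(N^3) brute-force agglomerative average linkage: at every step recompute
# the mean pairwise point distance between every pair of current clusters
# and merge the closest pair. Returns the merge heights in merge order.
bruteAverageHeights <- function(x) {
  D <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- NA; bj <- NA
    for (a in 2:length(clusters)) {
      for (b in 1:(a - 1L)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best - 1e-12) { best <- d; bi <- b; bj <- a }
      }
    }
    heights <- c(heights, best)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    clusters[[bi]] <- NULL
    clusters <- c(clusters, list(merged))
  }
  heights
}

# Brute-force widest-gap cut: try a cut height between every pair of
# consecutive distinct merge heights, score each cut by the height gap it
# sits in, and return the cluster count of the best cut (ties -> the
# earliest gap, i.e. the larger k).
bruteWidestGapK <- function(heights, nPoints) {
  u <- sort(unique(heights))
  if (length(u) < 2L) return(nPoints - sum(heights <= u[1L]) + 1L)
  gaps <- diff(u)
  j <- which.max(gaps)
  h <- (u[j] + u[j + 1L]) / 2
  nPoints - sum(heights <= h)
}

deriveSeedsForTest <- function(seed, n) dendrocut:::deriveSeeds(seed, n)

# Build a MergeSequence with prescribed heights over a chain merge tree
# (merge i joins the cluster so far with leaf i + 1); used to exercise the
# height-based estimators on hand-picked height sequences.
msFromHeights <- function(heights) {
  m <- length(heights)
  n <- m + 1L
  merge <- matrix(0L, m, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (m > 1L)
    for (i in 2:m) merge[i, ] <- c(i - 1L, -(i + 1L))
  new("MergeSequence", nPoints = n, heights = as.numeric(heights),
      merge = merge, order = seq_len(n), labels = character(0),
      linkage = "average", metric = "euclidean")
}
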