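# The height-based estimators are exercised on hand-picked merge-height
# sequences (via the chain-tree helper) and on random data against
# independent oracles.

test_that("elbow picks the merge with the largest second difference", {
  # accelerations at i = 3, 4 are 0 and 16 -> i* = 4 -> k = 4 + 2 - 4 = 2
  est <- elbowEstimate(msFromHeights(c(1, 2, 3, 20)))
  expect_identical(kHat(est), 2L)
  expect_identical(diagnostics(est)$argmaxIndex, 4L)
  expect_equal(diagnostics(est)$maxAcceleration, 16)
})

test_that("elbow ties break to the smallest merge index", {
  # perfectly linear heights: all accelerations zero -> i* = 3 -> k = 3
  expect_identical(kHat(elbowEstimate(msFromHeights(c(1, 2, 3, 4)))), 3L)
})

test_that("elbow needs at least 3 merges and never returns 1", {
  expect_error(elbowEstimate(msFromHeights(c(1, 2))), "insufficient merges")
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    ms <- computeLinkage(matrix(rnorm(n * 2), n, 2))
    k <- kHat(elbowEstimate(ms))
    expect_gte(k, 2L)
    expect_lte(k, n - 1L)
  }
  # any 3-merge input: argmax over {3} only -> k in {2, 3}
  expect_identical(kHat(elbowEstimate(msFromHeights(c(1, 1.1, 5)))), 2L)
})

test_that("maxdiff picks the merge after the largest height jump", {
  est <- maxDiffEstimate(msFromHeights(c(1.0, 1.1, 1.2, 9.0)))
  expect_identical(kHat(est), 2L)
  expect_equal(diagnostics(est)$maxDifference, 7.8)
  # single candidate
  expect_identical(kHat(maxDiffEstimate(msFromHeights(c(1, 9)))), 2L)
  # all-equal heights: every difference 0, tie -> i = 2 -> k = m
  expect_identical(kHat(maxDiffEstimate(msFromHeights(c(2, 2, 2, 2)))), 4L)
  expect_error(maxDiffEstimate(msFromHeights(1)), "insufficient merges")
})

test_that("maxdiff agrees with the brute-force widest-gap-cut oracle", {
  set.seed(29)
  for (rep in 1:12) {
    n <- sample(4:15, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    ms <- computeLinkage(x)
    expect_identical(kHat(maxDiffEstimate(ms)),
                     as.integer(bruteWidestGapK(mergeHeights(ms), n)))
  }
})

test_that("maxdiff never returns 1 but handles singleton clusters", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    ms <- computeLinkage(matrix(rnorm(n * 2), n, 2))
    expect_gte(kHat(maxDiffEstimate(ms)), 2L)
  }
  # an extreme outlier forms a singleton cluster at k = 2
  x <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2), c(50, 50))
  ms <- computeLinkage(x)
  expect_identical(kHat(maxDiffEstimate(ms)), 2L)
  expect_identical(sum(cutToK(ms, 2) == cutToK(ms, 2)[11]), 1L)
})

test_that("mode thresholds the dendrogram at modal height + alpha * sd", {
  ms <- msFromHeights(c(1, 1, 1, 1, 10))
  # 3 bins over [1, 10]: counts (4, 0, 1) -> modal midpoint 2.5; sd = 4.0249
  est3 <- modeEstimate(ms, alpha = 3)
  expect_equal(diagnostics(est3)$modalHeight, 2.5)
  expect_equal(diagnostics(est3)$sdHeights, sd(c(1, 1, 1, 1, 10)))
  expect_identical(kHat(est3), 1L)   # threshold 14.57 exceeds every height
  est0 <- modeEstimate(ms, alpha = 0)
  expect_identical(kHat(est0), 2L)   # threshold 2.5: only unit merges apply
})

test_that("mode handles an all-equal height sequence (sd = 0)", {
  est <- modeEstimate(msFromHeights(c(2, 2, 2, 2)), alpha = 0)
  expect_identical(kHat(est), 1L)    # threshold = common height, all applied
  expect_equal(diagnostics(est)$sdHeights, 0)
  expect_error(modeEstimate(msFromHeights(1)), "insufficient merges")
  expect_error(modeEstimate(msFromHeights(c(1, 2)), alpha = -1), "alpha")
})

test_that("within-cluster dispersion matches closed forms", {
  # two points at distance d in one cluster -> W = d/2
  expect_equal(withinClusterDispersion(cbind(c(0, 3)), c(1, 1)), 1.5)
  # all singletons -> 0
  expect_equal(withinClusterDispersion(cbind(c(0, 1, 2)), 1:3), 0)
  # three collinear points 0, 1, 2 in one cluster -> 4/3
  expect_equal(withinClusterDispersion(cbind(c(0, 1, 2)), c(1, 1, 1)), 4 / 3)
  # accepts a dist and a full distance matrix equally
  x <- matrix(rnorm(20), 10, 2)
  labs <- rep(1:2, 5)
  w <- withinClusterDispersion(x, labs)
  expect_equal(withinClusterDispersion(dist(x), labs), w)
  expect_equal(withinClusterDispersion(as.matrix(dist(x)), labs), w)
  expect_error(withinClusterDispersion(x, rep(c(1L, 3L), 5)), "empty cluster")
})

test_that("height-based estimators are invariant to rigid translation", {
  set.seed(37)
  x <- matrix(rnorm(60), 30, 2)
  shift <- matrix(rep(c(17, -9), each = 30), 30, 2)
  for (fn in list(elbowEstimate, maxDiffEstimate, modeEstimate)) {
    expect_identical(kHat(fn(computeLinkage(x))),
                     kHat(fn(computeLinkage(x + shift))))
  }
})

test_that("well-separated clusters are recovered exactly by elbow and maxdiff", {
  # four clusters on a square of side 20: unambiguous structure
  seeds <- 1000 + 1:15
  for (s in seeds) {
    x <- generateClusters(4, pointsPerCluster = 50, separation = 20, seed = s)
    ms <- computeLinkage(x)
    expect_identical(kHat(elbowEstimate(ms)), 4L)
    expect_identical(kHat(maxDiffEstimate(ms)), 4L)
  }
})

test_that("estimateK dispatches to the right estimator", {
  x <- generateClusters(2, pointsPerCluster = 30, seed = 3)
  ms <- computeLinkage(x)
  expect_identical(kHat(estimateK(x, "maxdiff")), kHat(maxDiffEstimate(ms)))
  expect_identical(kHat(estimateK(dist(x), "elbow")), kHat(elbowEstimate(ms)))
  expect_error(estimateK(dist(x), "gap"), "data matrix")
})
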