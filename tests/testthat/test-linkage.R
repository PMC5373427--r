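test_that("average linkage on three collinear points gives hand-computed heights", {
  ms <- computeLinkage(cbind(c(0, 1, 10)))
  # first merge {0,1} at distance 1; {0,1} to {10}: mean(10, 9) = 9.5
  expect_equal(mergeHeights(ms), c(1, 9.5))
  expect_identical(nPoints(ms), 3L)
})

test_that("identical points merge at height zero", {
  ms <- computeLinkage(rbind(c(1, 2), c(1, 2)))
  expect_equal(mergeHeights(ms), 0)
})

test_that("N points always produce N-1 non-decreasing non-negative heights", {
  set.seed(41)
  for (n in c(4, 7, 10)) {
    ms <- computeLinkage(matrix(rnorm(n * 3), n, 3))
    h <- mergeHeights(ms)
    expect_length(h, n - 1L)
    expect_true(all(diff(h) >= 0))
    expect_true(all(h >= 0))
  }
})

test_that("linkage heights agree with the O(N^3) brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    expect_equal(mergeHeights(computeLinkage(x)), bruteAverageHeights(x),
                 tolerance = 1e-10)
  }
})

test_that("linkage rejects degenerate input", {
  expect_error(computeLinkage(cbind(1)), "at least 2")
  expect_error(computeLinkage(rbind(c(1, NA), c(0, 0))), "non-finite")
  expect_error(computeLinkage(rbind(c(1, Inf), c(0, 0))), "non-finite")
})

test_that("cutToK returns exactly k non-empty clusters for every k", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(3:9, 1)
    ms <- computeLinkage(matrix(rnorm(n * 2), n, 2))
    for (k in 1:n) {
      labs <- cutToK(ms, k)
      expect_length(labs, n)
      expect_setequal(unique(labs), seq_len(k))
    }
  }
  ms <- computeLinkage(matrix(rnorm(10), 5, 2))
  expect_error(cutToK(ms, 0), "in \\[1")
  expect_error(cutToK(ms, 6), "in \\[1")
})

test_that("cutToK at k=2 separates the outlier in the 3-point example", {
  ms <- computeLinkage(cbind(c(0, 1, 10)))
  labs <- cutToK(ms, 2)
  expect_identical(labs[1], labs[2])
  expect_false(labs[3] == labs[1])
})

test_that("cutAtHeight applies exactly the merges at or below the threshold", {
  ms <- computeLinkage(cbind(c(0, 1, 10)))
  expect_identical(max(cutAtHeight(ms, 0.5)), 3L)   # below min height
  expect_identical(max(cutAtHeight(ms, 5)), 2L)     # one merge <= 5
  expect_identical(max(cutAtHeight(ms, 100)), 1L)   # above max height
  expect_identical(max(cutAtHeight(ms, 1)), 2L)     # boundary is inclusive
  expect_error(cutAtHeight(ms, -1), "non-negative")
})

test_that("cutAtHeight is monotone: higher cuts give fewer clusters", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    ms <- computeLinkage(matrix(rnorm(n * 2), n, 2))
    hs <- sort(c(0, mergeHeights(ms) + 1e-9, runif(5, 0, max(mergeHeights(ms)) * 1.2)))
    ks <- vapply(hs, function(h) max(cutAtHeight(ms, h)), integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("mergeTable has the (N-1) x 4 linkage layout with correct sizes", {
  set.seed(5)
  n <- 8L
  ms <- computeLinkage(matrix(rnorm(n * 2), n, 2))
  mt <- mergeTable(ms)
  expect_identical(dim(mt), c(n - 1L, 4L))
  expect_named(mt, c("child_a", "child_b", "height", "size"))
  expect_equal(mt$height, mergeHeights(ms))
  expect_identical(mt$size[n - 1L], n)        # last merge holds everything
  expect_true(all(mt$size >= 2))
})

test_that("a MergeSequence converts back to a plottable hclust", {
  x <- matrix(rnorm(12), 6, 2)
  ms <- computeLinkage(x)
  hc <- as.hclust(ms)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, mergeHeights(ms))
  expect_identical(stats::cutree(hc, 3), cutToK(ms, 3))
})
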