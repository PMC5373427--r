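test_that("generateClusters produces the expected layout", {
  x <- generateClusters(4, seed = 1)
  expect_identical(dim(x), c(400L, 2L))
  expect_identical(attr(x, "trueCluster"), rep(1:4, each = 100))
  # fixed seed: bit-identical on re-run
  expect_identical(generateClusters(4, seed = 1), x)
  expect_false(identical(generateClusters(4, seed = 2), x))
})

test_that("a single cluster concentrates around the first center (-3, -3)", {
  # mean of 100 unit-variance draws: |mean - center| <= 4/sqrt(100) per
  # coordinate with probability ~0.9999
  for (s in 1:20) {
    x <- generateClusters(1, seed = 3000 + s)
    expect_true(all(abs(colMeans(x) - c(-3, -3)) <= 0.4))
  }
})

test_that("cluster centers follow the square arrangement and scales apply", {
  x <- generateClusters(4, pointsPerCluster = 2000, separation = 10,
                        covScales = c(1, 1, 2, 0.5), seed = 17)
  g <- attr(x, "trueCluster")
  centers <- rbind(c(-5, -5), c(5, 5), c(-5, 5), c(5, -5))
  for (r in 1:4) {
    expect_true(all(abs(colMeans(x[g == r, ]) - centers[r, ]) < 0.15))
    expect_equal(mean(apply(x[g == r, ], 2, var)), c(1, 1, 2, 0.5)[r],
                 tolerance = 0.12)
  }
})

test_that("generateClusters validates its scenario", {
  expect_error(generateClusters(5), "default centers")
  expect_error(generateClusters(2, covScales = c(1, -1)), "positive")
  expect_error(generateClusters(3, dim = 3), "default centers")
  x <- generateClusters(3, dim = 3, centers = diag(3) * 4,
                        pointsPerCluster = 10, seed = 1)
  expect_identical(dim(x), c(30L, 3L))
})

test_that("successRate counts exact matches", {
  expect_equal(successRate(c(4, 4, 3, 4), 4), 0.75)
  expect_equal(successRate(c(2, 2), 2), 1)
  expect_equal(successRate(c(1, 3), 2), 0)
  expect_error(successRate(integer(0), 2), "no estimates")
})

test_that("errorSize averages |k - kHat| over the wrong runs only", {
  expect_equal(errorSize(c(4, 4, 3, 6), 4), 1.5)
  expect_equal(errorSize(c(4, 4), 4), 0)    # empty-set convention
  expect_equal(errorSize(1, 4), 3)
  expect_error(errorSize(integer(0), 4), "no estimates")
})

test_that("success and error identities hold on random estimate vectors", {
  set.seed(47)
  for (rep in 1:20) {
    est <- sample(1:6, 30, replace = TRUE)
    k <- sample(1:6, 1)
    s <- successRate(est, k)
    e <- errorSize(est, k)
    expect_gte(s, 0); expect_lte(s, 1); expect_gte(e, 0)
    expect_identical(s == 1, e == 0)
  }
})

test_that("runExperiment summarises a single run as indicator values", {
  res <- runExperiment(2, methods = c("elbow", "maxdiff"), nRuns = 1,
                       pointsPerCluster = 30, seed = 5)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$success_rate %in% c(0, 1)))
  expect_true(all(res$n_runs == 1L))
})

test_that("runExperiment is reproducible and internally consistent", {
  r1 <- runExperiment(3, methods = c("elbow", "maxdiff", "mode"), nRuns = 8,
                      pointsPerCluster = 40, seed = 11)
  r2 <- runExperiment(3, methods = c("elbow", "maxdiff", "mode"), nRuns = 8,
                      pointsPerCluster = 40, seed = 11)
  expect_identical(r1, r2)
  # S = 1 forces mean kHat = kTrue and zero error
  perfect <- r1[r1$success_rate == 1, ]
  if (nrow(perfect)) {
    expect_true(all(perfect$mean_k_hat == perfect$k_true))
    expect_true(all(perfect$error_size == 0))
    expect_true(all(perfect$n_wrong == 0L))
  }
  expect_true(all(r1$success_rate >= 0 & r1$success_rate <= 1))
  expect_true(all(r1$error_size >= 0))
  expect_true(all((r1$success_rate == 1) == (r1$error_size == 0)))
})

test_that("success improves with separation for elbow and maxdiff", {
  lo <- runExperiment(4, methods = c("elbow", "maxdiff"), nRuns = 100,
                      separation = 4, seed = 303)
  hi <- runExperiment(4, methods = c("elbow", "maxdiff"), nRuns = 100,
                      separation = 10, seed = 303)
  for (m in c("elbow", "maxdiff"))
    expect_gte(hi$success_rate[hi$method == m],
               lo$success_rate[lo$method == m])
})

test_that("separationSweep stacks per-separation summaries", {
  sw <- separationSweep(c(6, 20), kTrue = 2, methods = "maxdiff", nRuns = 3,
                        pointsPerCluster = 20, seed = 9)
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$separation, c(6, 20))
  one <- runExperiment(2, methods = "maxdiff", nRuns = 3,
                       pointsPerCluster = 20, separation = 6,
                       seed = deriveSeedsForTest(9, 2)[1])
  expect_equal(sw$success_rate[1], one$success_rate)
  expect_error(separationSweep(c(-1, 2), kTrue = 2), "positive")
})

test_that("mixing inside runExperiment pairs methods on shared subsamples", {
  res <- runExperiment(2, methods = c("elbow", "maxdiff"), nRuns = 3,
                       pointsPerCluster = 30, resampling = "mixing",
                       L = 10, seed = 13)
  expect_identical(res$method, c("elbow+mixing", "maxdiff+mixing"))
  res2 <- runExperiment(2, methods = c("elbow", "maxdiff"), nRuns = 3,
                        pointsPerCluster = 30, resampling = "mixing",
                        L = 10, seed = 13)
  expect_identical(res, res2)
})
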