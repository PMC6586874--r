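# Adaptive binning and the quadratic-form metric.

test_that("binning depth follows the 2 ln N events-per-bin rule", {
  set.seed(51)
  a <- matrix(stats::rnorm(3000), 1000, 3)
  b <- matrix(stats::rnorm(3000), 1000, 3)
  bi <- adaptive_bin(a, b)
  expect_equal(bi$L, 7L)   # round(log2(2000 / (2 ln 1000)))
  expect_equal(bi$B, 128L)
  # Mean occupancy within a factor of two of 2 ln N.
  expect_lt(mean(bi$counts), 2 * 2 * log(1000))
  expect_gt(mean(bi$counts), 0.5 * 2 * log(1000))

  tiny <- adaptive_bin(matrix(stats::rnorm(8), 4, 2),
                       matrix(stats::rnorm(8), 4, 2))
  expect_equal(tiny$L, 2L)  # round(log2(8 / (2 ln 4)))
  expect_equal(tiny$B, 4L)
})

test_that("the shared split tree partitions both samples", {
  set.seed(52)
  a <- matrix(stats::rnorm(2000, 0, 2), 500, 4)
  b <- matrix(stats::rnorm(1600, 1, 2), 400, 4)
  bi <- adaptive_bin(a, b)
  ba <- assign_bins(bi, a)
  bb <- assign_bins(bi, b)
  expect_true(all(ba >= 1L & ba <= bi$B))
  expect_true(all(bb >= 1L & bb <= bi$B))
  expect_equal(sum(tabulate(c(ba, bb), bi$B)), 900L)
  expect_equal(tabulate(c(ba, bb), bi$B), bi$counts)
})

test_that("events equal to a split threshold go to the right child", {
  # Duplicated median value: the first split threshold equals 2.
  a <- matrix(c(1, 2, 2, 5), 4, 1)
  b <- matrix(c(1, 2, 2, 5), 4, 1)
  bi <- adaptive_bin(a, b)
  expect_gte(bi$L, 1L)
  thr <- bi$thr[1]
  at_thr <- assign_bins(bi, matrix(thr, 1, 1))
  below <- assign_bins(bi, matrix(thr - 1e-9, 1, 1))
  expect_gt(at_thr, bi$B / 2)   # right subtree
  expect_lte(below, bi$B / 2)   # left subtree
})

test_that("cluster distributions are proper frequencies on the shared bins", {
  set.seed(53)
  a <- matrix(stats::rnorm(3000), 1000, 3)
  b <- matrix(stats::rnorm(3000), 1000, 3)
  bi <- adaptive_bin(a, b)
  f <- bin_cluster(bi, a, 1:400)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f >= 0))
  expect_error(bin_cluster(bi, a, integer(0)), "empty input")
  # The whole merged sample reproduces the bin occupancy proportions.
  fm <- bin_cluster(bi, rbind(a, b), seq_len(2000))
  expect_equal(fm, bi$counts / 2000, tolerance = 1e-12)
})

test_that("quadratic form distance agrees with the brute-force double sum", {
  set.seed(54)
  for (B in c(3L, 8L, 32L)) {
    cent <- matrix(stats::rnorm(B * 3), B, 3)
    d <- as.matrix(stats::dist(cent))
    A <- 1 - d / max(d)
    f <- stats::runif(B); f <- f / sum(f)
    g <- stats::runif(B); g <- g / sum(g)
    brute <- 0
    for (i in seq_len(B)) for (j in seq_len(B)) {
      brute <- brute + (f[i] - g[i]) * (f[j] - g[j]) * A[i, j]
    }
    brute <- sqrt(max(0, brute))
    expect_equal(qf_distance(f, g, A), brute, tolerance = 1e-12)
    expect_equal(qf_distance(g, f, A), qf_distance(f, g, A))
    expect_equal(qf_distance(f, f, A), 0)
    expect_gt(qf_distance(f, g, A), 0)
  }
  expect_error(qf_distance(c(1, 0), c(0, 1), diag(3)), "shape error")
})

test_that("hand-computed two-bin case gives sqrt(2) under identity similarity", {
  expect_equal(qf_distance(c(1, 0), c(0, 1), diag(2)), sqrt(2),
               tolerance = 1e-12)
})

test_that("the metric satisfies the triangle inequality on random histograms", {
  set.seed(55)
  B <- 12L
  cent <- matrix(stats::rnorm(B * 2), B, 2)
  d <- as.matrix(stats::dist(cent))
  A <- 1 - d / max(d)
  for (rep in 1:50) {
    f <- stats::runif(B); f <- f / sum(f)
    g <- stats::runif(B); g <- g / sum(g)
    h <- stats::runif(B); h <- h / sum(h)
    expect_lte(qf_distance(f, h, A),
               qf_distance(f, g, A) + qf_distance(g, h, A) + 1e-12)
  }
})

test_that("moving mass to farther bins increases the distance", {
  B <- 10L
  cent <- matrix(c(seq_len(B), rep(0, B)), B, 2)  # bins on a line
  d <- as.matrix(stats::dist(cent))
  A <- 1 - d / max(d)
  f <- c(1, rep(0, B - 1L))
  dists <- vapply(2:B, function(k) {
    g <- rep(0, B); g[k] <- 1
    qf_distance(f, g, A)
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("bin similarity is a proper unit-diagonal similarity", {
  set.seed(56)
  a <- matrix(stats::rnorm(1000), 500, 2)
  b <- matrix(stats::rnorm(1000), 500, 2)
  bi <- adaptive_bin(a, b)
  A <- bin_similarity(bi)
  expect_equal(diag(A), rep(1, bi$B))
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A, t(A))
  expect_equal(min(A), 0)  # the farthest centroid pair
})

test_that("empty samples are rejected", {
  expect_error(adaptive_bin(matrix(numeric(0), 0, 2),
                            matrix(stats::rnorm(10), 5, 2)), "empty input")
})
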