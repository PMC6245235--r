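test_that("resampling honours size, distinctness, determinism, and the full-sample case", {
  full <- resampleIndices(10, fraction = 1, b = 3, seed = 1)
  expect_true(all(vapply(full, identical, TRUE, 1:10)))
  sub <- resampleIndices(10, fraction = 0.8, b = 10, seed = 5)
  expect_length(sub, 10)
  expect_true(all(lengths(sub) == 8))
  expect_true(all(vapply(sub, anyDuplicated, 0L) == 0L))
  expect_identical(sub, resampleIndices(10, fraction = 0.8, b = 10, seed = 5))
  boot <- resampleIndices(10, fraction = 1, withReplacement = TRUE, b = 5,
                          seed = 2)
  expect_true(all(lengths(boot) == 10))
  expect_error(resampleIndices(2), "at least 3")
})

test_that("lloydKmeans solves trivial geometries and repairs empty clusters", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  p <- lloydKmeans(pts, 2, seed = 1)
  expect_equal(p@labels[1], p@labels[2])
  expect_equal(p@labels[3], p@labels[4])
  expect_false(p@labels[1] == p@labels[3])
  one <- lloydKmeans(pts, 1, seed = 1)
  expect_equal(attr(one, "sse"), sum(sweep(pts, 2, colMeans(pts))^2))
  expect_error(lloydKmeans(pts, 5, seed = 1), "exceed")
})

test_that("lloydKmeans with restarts attains the exhaustive optimum on small instances", {
  for (s in 1:25) {
    set.seed(s)
    m <- sample(4:8, 1)
    X <- matrix(rnorm(m * 2), m, 2)
    p <- lloydKmeans(X, 2, seed = s, restarts = 50)
    expect_equal(attr(p, "sse"), oracleBestSse2(X), tolerance = 1e-8)
  }
})

test_that("kmeans is deterministic given the seed", {
  X <- matrix(rnorm(60), 30, 2)
  a <- lloydKmeans(X, 3, seed = 9)
  b <- lloydKmeans(X, 3, seed = 9)
  expect_identical(a@labels, b@labels)
})

test_that("pamPartition picks data-point medoids and matches brute force at m = 7", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(5, 5), c(5, 5.1))
  p <- pamPartition(pts, 2)
  med <- attr(p, "medoids")
  expect_length(med, 2)
  expect_true(all(p@labels[1:2] == p@labels[1]))
  expect_true(p@labels[1] != p@labels[3])
  allOwn <- pamPartition(pts, 4)
  expect_equal(attr(allOwn, "cost"), 0)
  # BUILD+SWAP reaches the same solutions as the reference implementation;
  # where that solution is the brute-force optimum (the usual case on tiny
  # instances) it must match it exactly
  nOpt <- 0L
  for (s in 1:25) {
    set.seed(100 + s)
    m <- sample(5:8, 1)
    X <- matrix(rnorm(m * 2), m, 2)
    p <- pamPartition(X, 2)
    ref <- unname(cluster::pam(X, 2)$objective["swap"] * m)
    expect_equal(attr(p, "cost"), ref, tolerance = 1e-9)
    if (abs(ref - oraclePamCost(X, 2)) < 1e-9) nOpt <- nOpt + 1L
  }
  expect_gt(nOpt, 20)  # the heuristic is optimal on most tiny instances
})

test_that("agglomerative partitions match a naive bottom-up merger", {
  naiveAgglo <- function(X, k, linkage) {
    groups <- as.list(seq_len(nrow(X)))
    D <- as.matrix(dist(X))
    linkDist <- function(a, b) {
      d <- D[a, b, drop = FALSE]
      switch(linkage, single = min(d), complete = max(d), average = mean(d))
    }
    while (length(groups) > k) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (i >= j) next
        d <- linkDist(groups[[i]], groups[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    lab <- integer(nrow(X))
    for (i in seq_along(groups)) lab[groups[[i]]] <- i
    lab
  }
  for (linkage in c("single", "complete", "average")) {
    set.seed(7)
    X <- matrix(rnorm(20), 10, 2)
    p <- agglomerativePartition(X, 3, linkage)
    expect_equal(adjRand(p@labels, naiveAgglo(X, 3, linkage)), 1,
                 info = linkage)
  }
  line <- matrix(c(0, 1, 10, 11), ncol = 1)
  p <- agglomerativePartition(line, 2, "single")
  expect_equal(p@labels[1], p@labels[2])
  expect_equal(p@labels[3], p@labels[4])
  singl <- agglomerativePartition(line, 4)
  expect_equal(sort(singl@labels), 1:4)
})
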