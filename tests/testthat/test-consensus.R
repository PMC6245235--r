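test_that("agreement matrix counts co-clustering and joint presence correctly", {
  # identical full-data partitions: coCluster = B for co-members, 0 otherwise
  part <- new("Partition", itemIds = 1:4, labels = c(1L, 1L, 2L, 2L), k = 2L)
  A <- buildAgreementMatrix(rep(list(part), 5), rep(list(1:4), 5), 4)
  expect_true(all(A@coPresent == 5))
  expect_equal(A@coCluster[1, 2], 5L)
  expect_equal(A@coCluster[1, 3], 0L)
  expect_equal(A@ratio[1, 2], 1)
  # a pair never jointly sampled has zero evidence
  p1 <- new("Partition", itemIds = 1:2, labels = c(1L, 1L), k = 1L)
  p2 <- new("Partition", itemIds = 1:2, labels = c(1L, 1L), k = 1L)
  A2 <- buildAgreementMatrix(list(p1, p2), list(1:2, 3:4), 4)
  expect_equal(A2@coPresent[1, 3], 0L)
  expect_equal(A2@ratio[1, 3], 0)
  expect_error(buildAgreementMatrix(list(p1), list(4:5), 4), "outside")
})

test_that("agreement matrix equals the brute-force pair count on random instances", {
  for (s in 1:30) {
    set.seed(200 + s)
    n <- sample(8:30, 1)
    b <- sample(2:10, 1)
    cols <- lapply(seq_len(b), function(i) sort(sample(n, max(2, round(0.8 * n)))))
    parts <- lapply(cols, function(idx)
      new("Partition", itemIds = seq_along(idx),
          labels = sample(1:3, length(idx), replace = TRUE), k = 3L))
    A <- buildAgreementMatrix(parts, cols, n)
    o <- oracleAgreement(parts, cols, n)
    expect_identical(A@coCluster, o$coCluster)
    expect_identical(A@coPresent, o$coPresent)
  }
})

test_that("consensus recovers block structure and is invariant to input order", {
  blocks <- rep(1:3, each = 4)
  ratio <- outer(blocks, blocks, function(a, b) as.numeric(a == b))
  A <- new("AgreementMatrix", n = 12L, b = 1L,
           coCluster = matrix(as.integer(ratio), 12, 12),
           coPresent = matrix(1L, 12, 12), ratio = ratio)
  p <- consensusPartition(A, 3, seed = 4)
  expect_equal(adjRand(p@labels, blocks), 1)
  one <- consensusPartition(A, 1, seed = 4)
  expect_equal(one@k, 1L)
  # order invariance of the full pipeline's matrix
  set.seed(42)
  cols <- replicate(6, sort(sample(15, 12)), simplify = FALSE)
  parts <- lapply(cols, function(idx)
    new("Partition", itemIds = seq_along(idx),
        labels = sample(1:2, length(idx), replace = TRUE), k = 2L))
  A1 <- buildAgreementMatrix(parts, cols, 15)
  ord <- sample(6)
  A2 <- buildAgreementMatrix(parts[ord], cols[ord], 15)
  expect_identical(A1@ratio, A2@ratio)
})

test_that("with one full-fraction resample the consensus is that single clustering", {
  tab <- randomCohort(40, seed = 11)
  cc <- consensusCluster(tab, k = 3, b = 1, fraction = 1, seed = 11)
  base <- lloydKmeans(cc$Xs, 3, seed = substreamSeed(11, "base1"),
                      restarts = 1, init = "random")
  expect_true(all(cc$agreement@ratio %in% c(0, 1)))
  expect_equal(adjRand(cc$partition@labels, base@labels), 1)
})

test_that("agreement matrix round-trips through CSV", {
  part <- new("Partition", itemIds = 1:4, labels = c(1L, 2L, 1L, 2L), k = 2L)
  A <- buildAgreementMatrix(list(part), list(1:4), 4)
  path <- tempfile(fileext = ".csv")
  writeAgreementCsv(A, path)
  expect_equal(readAgreementCsv(path), A@ratio)
})

test_that("kappa is 1 under label permutation and near 0 for independent partitions", {
  set.seed(31)
  lab <- sample(1:3, 200, replace = TRUE)
  p <- new("Partition", itemIds = 1:200, labels = as.integer(lab), k = 3L)
  q <- new("Partition", itemIds = 1:200,
           labels = as.integer(c(2L, 3L, 1L)[lab]), k = 3L)
  expect_equal(kappaAgreement(p, p), 1)
  expect_equal(kappaAgreement(p, q), 1)
  r <- new("Partition", itemIds = 1:200,
           labels = sample(1:3, 200, replace = TRUE), k = 3L)
  expect_lt(abs(kappaAgreement(p, r)), 0.15)
  bad <- new("Partition", itemIds = 2:201, labels = p@labels, k = 3L)
  expect_error(kappaAgreement(p, bad), "identical item sets")
})

test_that("aligned kappa matches e1071's kappa on pre-aligned labels", {
  set.seed(77)
  a <- sample(1:3, 300, replace = TRUE)
  b <- ifelse(runif(300) < 0.7, a, sample(1:3, 300, replace = TRUE))
  p <- new("Partition", itemIds = 1:300, labels = as.integer(a), k = 3L)
  q <- new("Partition", itemIds = 1:300, labels = as.integer(b), k = 3L)
  # b was generated aligned to a, so optimal matching is the identity and
  # kappaAgreement must equal plain Cohen's kappa from an independent source
  expect_equal(kappaAgreement(p, q),
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-12)
})

test_that("kappa handles partitions with unequal cluster counts", {
  a <- rep(1:2, each = 10)
  b <- c(rep(1, 10), rep(2, 5), rep(3, 5))
  p <- new("Partition", itemIds = 1:20, labels = as.integer(a), k = 2L)
  q <- new("Partition", itemIds = 1:20, labels = as.integer(b), k = 3L)
  k <- kappaAgreement(p, q)
  expect_gt(k, 0.4)
  expect_lt(k, 1)
})
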