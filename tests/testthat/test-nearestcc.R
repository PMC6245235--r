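test_that("linkage distances follow min / max / mean of Euclidean distances", {
  members <- rbind(c(0, 0), c(4, 0))
  expect_equal(linkageDistance(c(1, 0), members, "single"), 1)
  expect_equal(linkageDistance(c(1, 0), members, "complete"), 3)
  expect_equal(linkageDistance(c(1, 0), members, "average"), 2)
  expect_equal(linkageDistance(c(0, 0), members, "single"), 0)
  expect_error(linkageDistance(c(0, 0), members[0, , drop = FALSE]), "members")
  # brute-force cross-check on random instances
  for (s in 1:10) {
    set.seed(500 + s)
    M <- matrix(rnorm(24), 8, 3); x <- rnorm(3)
    d <- apply(M, 1, function(r) sqrt(sum((r - x)^2)))
    expect_equal(linkageDistance(x, M, "single"), min(d))
    expect_equal(linkageDistance(x, M, "complete"), max(d))
    expect_equal(linkageDistance(x, M, "average"), mean(d))
  }
})

test_that("routing sends points to the nearest cluster with low-label ties", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 8)
  model <- fitNearestCC(sim$table, seed = 8)
  Xs <- applyScaler(model@scaler,
                    featureMatrix(imputeCohort(sim$table,
                                               model@config$imputeStats)))
  # every training row routes to its own cluster under single linkage
  for (cl in model@clusters) {
    i <- match(cl$rowIds[1], sim$table@rowIds)
    expect_equal(routeCluster(Xs[i, ], model), cl$label)
  }
  # brute-force distance scan agrees
  for (i in sample(nrow(Xs), 10)) {
    d <- vapply(model@clusters, function(cl)
      linkageDistance(Xs[i, ], cl$members, model@linkage), 0)
    expect_equal(routeCluster(Xs[i, ], model),
                 model@clusters[[which.min(d)]]$label)
  }
})

test_that("k = 1 nearest consensus clustering reduces to the global tree", {
  sim <- generateCohort(defaultSscLikeSpec(n = 200L), seed = 13)
  m1 <- fitNearestCC(sim$table, k = 1, seed = 13)
  mg <- fitGlobalTree(sim$table, seed = 13)
  fresh <- generateCohort(defaultSscLikeSpec(n = 300L), seed = 14)$table
  expect_identical(predictNearestCC(m1, fresh), predictNearestCC(mg, fresh))
})

test_that("b = 1, fraction = 1 nearest-CC is functionally nearest K-means", {
  sim <- generateCohort(defaultSscLikeSpec(n = 200L), seed = 21)
  mcc <- fitNearestCC(sim$table, b = 1, fraction = 1, seed = 21)
  mkm <- fitNearestKmeans(sim$table, seed = 21)
  expect_equal(adjRand(mcc@consensus@labels, mkm@consensus@labels), 1)
  fresh <- generateCohort(defaultSscLikeSpec(n = 300L), seed = 22)$table
  expect_identical(predictNearestCC(mcc, fresh), predictNearestCC(mkm, fresh))
})

test_that("refitting with the same config and seed is byte-identical", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 5)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  writeNccModel(fitNearestCC(sim$table, seed = 5), p1)
  writeNccModel(fitNearestCC(sim$table, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("model snapshots reload to an equivalent predictor", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 6)
  model <- fitNearestCC(sim$table, seed = 6)
  path <- tempfile(fileext = ".json")
  writeNccModel(model, path)
  back <- readNccModel(path)
  fresh <- generateCohort(defaultSscLikeSpec(n = 200L), seed = 7)$table
  expect_identical(predictNearestCC(back, fresh),
                   predictNearestCC(model, fresh))
})

test_that("small consensus clusters defer to the fallback tree", {
  sim <- generateCohort(defaultSscLikeSpec(n = 120L), seed = 9)
  model <- fitNearestCC(sim$table, k = 3, minClusterSize = 200, seed = 9)
  expect_true(all(vapply(model@clusters, function(cl) is.null(cl$tree), TRUE)))
  fresh <- generateCohort(defaultSscLikeSpec(n = 100L), seed = 10)$table
  expect_identical(predictNearestCC(model, fresh),
                   predictNearestCC(fitGlobalTree(sim$table, seed = 9), fresh))
})

test_that("predictions stay within the training label set and dimensions are checked", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 19)
  model <- fitNearestCC(sim$table, seed = 19)
  fresh <- generateCohort(defaultSscLikeSpec(n = 80L), seed = 20)$table
  expect_true(all(predictNearestCC(model, fresh) %in% c("1", "2")))
  unlabeled <- sim$table
  unlabeled@y <- character(0)
  expect_error(fitNearestCC(unlabeled, seed = 1), "labeled")
  other <- randomCohort(10, d = 2, seed = 1)
  expect_error(predictNearestCC(model, other), "features")
})

test_that("per-cluster trees fit their own clusters better than the fallback fits the pool", {
  sim <- generateCohort(defaultSscLikeSpec(), seed = 33)
  model <- fitNearestCC(sim$table, seed = 33)
  tab <- imputeCohort(sim$table, model@config$imputeStats)
  Xs <- applyScaler(model@scaler, featureMatrix(tab))
  y <- classLabels(sim$table)
  accs <- vapply(model@clusters, function(cl) {
    idx <- match(cl$rowIds, sim$table@rowIds)
    mean(predictTree(cl$tree, Xs[idx, , drop = FALSE]) == y[idx])
  }, 0)
  fallbackAcc <- mean(predictTree(model@fallbackTree, Xs) == y)
  expect_gt(min(accs), 0.85)
  expect_lt(fallbackAcc, 0.85)
  expect_gt(min(accs), fallbackAcc)
})
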