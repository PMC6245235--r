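test_that("confusion metrics reproduce their definitions and NA conventions", {
  yt <- c(rep("1", 4), rep("2", 6))
  yp <- c("1", "1", "1", "2", "1", "1", "2", "2", "2", "2")
  m <- confusionMetrics(yt, yp)  # tp=3 fn=1 fp=2 tn=4
  expect_equal(c(m@tp, m@fn, m@fp, m@tn), c(3L, 1L, 2L, 4L))
  expect_equal(m@sensitivity, 0.75)
  expect_equal(m@specificity, 2 / 3, tolerance = 1e-4)
  expect_equal(m@precision, 0.6)
  expect_equal(m@recall, m@sensitivity)
  perfect <- confusionMetrics(yt, yt)
  expect_equal(perfect@accuracy, 1)
  expect_equal(perfect@errorRate, 0)
  # zero-denominator rates are NA, never 0
  allNeg <- confusionMetrics(c("2", "2"), c("2", "2"))
  expect_true(is.na(allNeg@sensitivity))
  expect_true(is.na(allNeg@precision))
  expect_error(confusionMetrics(c("1", "2", "3"), c("1", "2", "3")), "binary")
})

test_that("confusion metrics match caret on random label pairs", {
  for (s in 1:20) {
    set.seed(600 + s)
    yt <- sample(c("1", "2"), 200, replace = TRUE)
    yp <- sample(c("1", "2"), 200, replace = TRUE)
    m <- confusionMetrics(yt, yp, positive = "1")
    ref <- caret::confusionMatrix(factor(yp, c("1", "2")),
                                  factor(yt, c("1", "2")), positive = "1")
    expect_equal(m@sensitivity, unname(ref$byClass["Sensitivity"]),
                 tolerance = 1e-12)
    expect_equal(m@specificity, unname(ref$byClass["Specificity"]),
                 tolerance = 1e-12)
    expect_equal(m@precision, unname(ref$byClass["Precision"]),
                 tolerance = 1e-12)
    expect_equal(m@accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-12)
  }
})

test_that("welch t matches the hand formula, is antisymmetric, and detects separation", {
  handWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
  }
  set.seed(71)
  a <- rnorm(12); b <- rnorm(15, 0.4)
  w <- welchT(a, b)
  h <- handWelch(a, b)
  expect_equal(w$t, h$t, tolerance = 1e-10)
  expect_equal(w$p, h$p, tolerance = 1e-10)
  expect_equal(welchT(b, a)$t, -w$t, tolerance = 1e-12)
  expect_equal(welchT(b, a)$p, w$p, tolerance = 1e-12)
  same <- welchT(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- welchT(a, a + 10 * sd(a))
  expect_lt(far$p, 1e-6)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("repeated holdout shares splits across methods and is reproducible", {
  sim <- generateCohort(defaultSscLikeSpec(n = 200L), seed = 44)
  twice <- list(nccMethod("global-tree"),
                within(nccMethod("global-tree"), name <- "global-tree-copy"))
  res <- repeatedHoldout(sim$table, twice, repeats = 4, seed = 44)
  expect_identical(errorVector(res, "global-tree"),
                   errorVector(res, "global-tree-copy"))
  res2 <- repeatedHoldout(sim$table, twice, repeats = 4, seed = 44)
  expect_identical(res@errors, res2@errors)
})

test_that("a majority-class predictor scores ~50% error on a balanced cohort", {
  set.seed(55)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("f1", "f2")))
  sc <- cohortSchema(colnames(X), "continuous", classColumn = "cls")
  tab <- cohortTable(X, sc, y = rep(c("1", "2"), 100))
  maj <- list(name = "majority",
              fit = function(train, seed) names(which.max(table(train@y))),
              predict = function(model, table) rep(model, nRows(table)))
  res <- repeatedHoldout(tab, list(maj), repeats = 10, seed = 3)
  expect_equal(mean(errorVector(res, "majority")), 0.5, tolerance = 0.06)
})

test_that("sweepK runs the grid, skips impossible K, and {1} equals the global tree", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 66)
  sw <- sweepK(sim$table, kValues = c(1, 2), repeats = 3, seed = 66)
  expect_setequal(unique(sw$k), c(1, 2))
  res <- repeatedHoldout(sim$table, list(nccMethod("global-tree")),
                         repeats = 3, seed = 66, clusterBars = FALSE)
  expect_equal(sw$error[sw$k == 1], errorVector(res, "global-tree"),
               tolerance = 1e-12)
  expect_warning(sweepK(sim$table, kValues = 1000, repeats = 2, seed = 1),
                 "skipping")
})

test_that("the comparison roster methods all run behind one interface", {
  sim <- generateCohort(defaultSscLikeSpec(n = 150L), seed = 77)
  methods <- lapply(c("pam-dt", "hier-dt", "svm", "svm-kmeans"), nccMethod)
  res <- repeatedHoldout(sim$table, methods, repeats = 2, seed = 77,
                         clusterBars = FALSE)
  errs <- aggregate(error ~ method, res@errors, mean)
  expect_setequal(errs$method, c("pam-dt", "hier-dt", "svm", "svm-kmeans"))
  expect_true(all(errs$error < 0.5))
  expect_error(nccMethod("boosting"), "valid methods")
})
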