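test_that("readCohort parses features, applies recode maps, and keeps unlabeled rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Hb,gender,cls", "12.1,1,1", "13.5,2,2", "11.9,2,"), csv)
  sc <- cohortSchema(c("Hb", "gender"), c("continuous", "binary"),
                     classColumn = "cls",
                     recodeMaps = list(gender = c("1" = 0, "2" = 1)))
  tab <- readCohort(csv, sc)
  expect_equal(nRows(tab), 3L)
  expect_equal(featureMatrix(tab)[, "gender"], c(0, 1, 1))
  expect_equal(classLabels(tab), c("1", "2", NA))
})

test_that("readCohort errors name the offending column and value", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("a,cls", "1,1"), csv)
  sc <- cohortSchema(c("a", "Hb"), "continuous", classColumn = "cls")
  expect_error(readCohort(csv, sc), "Hb")
  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("a,cls", "oops,1"), csv2)
  sc2 <- cohortSchema("a", "continuous", classColumn = "cls")
  expect_error(readCohort(csv2, sc2), "non-numeric.*'a'")
})

test_that("schema round-trips through its YAML config", {
  sc <- cohortSchema(c("Hb", "ACA"), c("continuous", "binary"),
                     classColumn = "cls", timeColumn = "t", eventColumn = "e",
                     positiveClass = "1",
                     recodeMaps = list(ACA = c("1" = 0, "2" = 1)))
  path <- tempfile(fileext = ".yaml")
  writeSchema(sc, path)
  sc2 <- readSchema(path)
  expect_equal(sc2@featureNames, sc@featureNames)
  expect_equal(sc2@featureKinds, sc@featureKinds)
  expect_equal(sc2@classColumn, sc@classColumn)
  expect_equal(sc2@recodeMaps$ACA, sc@recodeMaps$ACA)
})

test_that("cohort CSV write/read round-trip is exact", {
  sim <- generateCohort(defaultSscLikeSpec(n = 40L), seed = 3)
  path <- tempfile(fileext = ".csv")
  writeCohortCsv(sim$table, path)
  back <- readCohort(path, sim$table@schema)
  expect_identical(back@X, sim$table@X)
  expect_identical(back@y, sim$table@y)
  expect_identical(back@time, sim$table@time)
  expect_identical(back@event, sim$table@event)
})

test_that("imputation fills continuous gaps with medians, binary with modes (ties to 0)", {
  sc <- tinySchema()
  X <- rbind(c(1, 0), c(NA, 0), c(3, 1), c(2, NA))
  colnames(X) <- c("a", "b")
  tab <- cohortTable(X, sc)
  out <- imputeCohort(tab)
  expect_equal(unname(featureMatrix(out)[2, "a"]), 2)  # median of 1,3,2
  expect_equal(unname(featureMatrix(out)[4, "b"]), 0)  # mode of 0,0,1
  expect_true(anyNA(featureMatrix(tab)))       # input untouched
  clean <- imputeCohort(out)
  expect_identical(featureMatrix(clean), featureMatrix(out))  # idempotent
  allNa <- cohortTable(rbind(c(NA, 1), c(NA, 0)), sc)
  expect_error(imputeCohort(allNa), "entirely missing")
})

test_that("scaler standardizes continuous features and passes binaries through", {
  sc <- tinySchema()
  tab <- cohortTable(cbind(a = c(0, 2, 4, 9), b = c(0, 1, 1, 0)), sc)
  scal <- fitScaler(tab)
  Xs <- applyScaler(scal, featureMatrix(tab))
  expect_lt(abs(mean(Xs[, "a"])), 1e-9)
  expect_lt(abs(sd(Xs[, "a"]) - 1), 1e-9)
  expect_identical(Xs[, "b"], featureMatrix(tab)[, "b"])
  # two-point symmetry under the sample-sd convention
  two <- cohortTable(cbind(a = c(0, 2), b = c(0, 1)), sc)
  Xs2 <- applyScaler(fitScaler(two), featureMatrix(two))
  expect_equal(unname(Xs2[, "a"]), c(-1, 1) / sqrt(2))
  # constant columns map to zero
  cst <- cohortTable(cbind(a = c(5, 5, 5), b = c(0, 0, 1)), sc)
  expect_equal(unname(applyScaler(fitScaler(cst), featureMatrix(cst))[, "a"]),
               c(0, 0, 0))
  # applying twice is not refitting: test rows use the training scaler
  expect_error(applyScaler(scal, matrix(1, 2, 3)), "dimensionality")
})

test_that("time-to-event labeling implements the 5-year selection rule", {
  sc <- tinySchema(withSurvival = TRUE)
  tab <- cohortTable(cbind(a = 1:5, b = 0), sc,
                     time = c(30, 70, 40, 60, 60),
                     event = c(1L, 0L, 0L, 1L, 0L))
  lt <- labelTimeToEvent(tab, 60)
  expect_equal(lt$labels, c("1", "2", NA, "1", "2"))
  expect_equal(lt$included, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # retained rows carry exactly the two classes; excluded rows are exactly
  # the censored-before-threshold patients
  expect_setequal(unique(na.omit(lt$labels)), c("1", "2"))
  excl <- which(!lt$included)
  expect_true(all(tab@event[excl] == 0L & tab@time[excl] < 60))
  # negative times are rejected at the type level already
  expect_error(cohortTable(cbind(a = 1, b = 0), sc, time = -1, event = 1L),
               "nonnegative")
})
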