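#' Confusion-matrix metrics for a binary outcome
#'
#' Sensitivity = recall = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp), accuracy = (tp+tn)/total. A rate whose denominator is zero is
#' reported as NA, never as 0.
#'
#' @param yTrue,yPred equal-length binary label vectors.
#' @param positive the label counted as positive; default "1".
#' @return a \code{\linkS4class{ConfusionMetrics}}.
#' @export
confusionMetrics <- function(yTrue, yPred, positive = "1") {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(unique(yTrue)) > 2L || length(unique(yPred)) > 2L)
    stop("confusion metrics are defined for binary labels", call. = FALSE)
  tp <- sum(yTrue == positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  tn <- sum(yTrue != positive & yPred != positive)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  new("ConfusionMetrics", tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
      precision = rate(tp, tp + fp), recall = rate(tp, tp + fn),
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      errorRate = rate(fp + fn, tp + tn + fp + fn))
}

setMethod("show", "ConfusionMetrics", function(object) {
  cat(sprintf("ConfusionMetrics: tp=%d fp=%d tn=%d fn=%d\n", object@tp,
              object@fp, object@tn, object@fn))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  precision %.4f  accuracy %.4f\n",
              object@sensitivity, object@specificity, object@precision,
              object@accuracy))
})

#' Turn metrics into a one-row data frame
#' @param metrics a \code{\linkS4class{ConfusionMetrics}}.
#' @return data.frame of counts and rates.
#' @export
metricsAsDataFrame <- function(metrics) {
  data.frame(tp = metrics@tp, fp = metrics@fp, tn = metrics@tn,
             fn = metrics@fn, sensitivity = metrics@sensitivity,
             specificity = metrics@specificity, precision = metrics@precision,
             recall = metrics@recall, accuracy = metrics@accuracy,
             errorRate = metrics@errorRate)
}

#' Named classification methods for the comparison grid
#'
#' Returns a fit/predict pair behind a uniform interface. Native methods
#' ("nearest-cc", "nearest-kmeans", "global-tree", "hier-dt", "pam-dt") use
#' the package's partitioners and gain-ratio trees; "svm" and "svm-kmeans"
#' delegate the classifier to \pkg{e1071} (a non-native comparison slot).
#'
#' @param name one of "nearest-cc", "nearest-kmeans", "global-tree", "svm",
#'   "svm-kmeans", "hier-dt", "pam-dt".
#' @param ... method options forwarded to the fit function (k, linkage, ...).
#' @return list with elements \code{name}, \code{fit(train, seed)} and
#'   \code{predict(model, table)}.
#' @export
nccMethod <- function(name, ...) {
  opts <- list(...)
  known <- c("nearest-cc", "nearest-kmeans", "global-tree", "svm",
             "svm-kmeans", "hier-dt", "pam-dt")
  if (!name %in% known)
    stop("unknown method '", name, "'; valid methods: ",
         paste(known, collapse = ", "), call. = FALSE)
  stdPredict <- function(model, table) predictNearestCC(model, table)
  # forward only the options a fit function understands (a shared RunConfig
  # may carry k/b/fraction that the global tree, say, has no use for)
  usable <- function(fn, extra = character(0)) {
    keep <- setdiff(intersect(names(opts), c(names(formals(fn)), extra)),
                    c("train", "seed"))
    opts[keep]
  }
  fit <- switch(name,
    "nearest-cc" = function(train, seed)
      do.call(fitNearestCC, c(list(train = train, seed = seed),
                              usable(fitNearestCC))),
    "nearest-kmeans" = function(train, seed)
      do.call(fitNearestKmeans, c(list(train = train, seed = seed),
                                  usable(fitNearestKmeans))),
    "global-tree" = function(train, seed)
      do.call(fitGlobalTree, c(list(train = train, seed = seed),
                               usable(fitGlobalTree))),
    "hier-dt" = function(train, seed)
      do.call(fitClusterThenTree,
              c(list(train = train, seed = seed,
                     partitionFun = function(Xs, k, s)
                       agglomerativePartition(Xs, k,
                         linkage = opts$hclustLinkage %||% "average")),
                usable(fitClusterThenTree))),
    "pam-dt" = function(train, seed)
      do.call(fitClusterThenTree,
              c(list(train = train, seed = seed,
                     partitionFun = function(Xs, k, s) pamPartition(Xs, k, s)),
                usable(fitClusterThenTree))),
    "svm" = function(train, seed) fitSvmModel(train, NULL, seed, opts),
    "svm-kmeans" = function(train, seed)
      fitSvmModel(train, opts$k %||% 3L, seed, opts))
  pred <- if (name %in% c("svm", "svm-kmeans")) predictSvmModel else stdPredict
  list(name = name, fit = fit, predict = pred)
}

# SVM comparison slot (library-backed, behind the same interface)
fitSvmModel <- function(train, k, seed, opts) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the svm comparison methods require the e1071 package", call. = FALSE)
  checkLabeled(train)
  imp <- fitImputeStats(train)
  tab <- imputeCohort(train, imp)
  scaler <- fitScaler(tab)
  Xs <- applyScaler(scaler, tab@X)
  y <- factor(train@y)
  fitOne <- function(rows) {
    if (length(unique(y[rows])) < 2L) return(list(const = as.character(y[rows][1])))
    list(svm = e1071::svm(Xs[rows, , drop = FALSE], y[rows], scale = FALSE))
  }
  out <- list(scaler = scaler, imputeStats = imp,
              featureNames = train@schema@featureNames,
              linkage = opts$linkage %||% "single")
  if (is.null(k)) {
    out$global <- fitOne(seq_len(nrow(Xs)))
  } else {
    part <- lloydKmeans(Xs, k, seed = substreamSeed(seed, "base1"),
                        restarts = opts$baseRestarts %||% 1L,
                        init = opts$baseInit %||% "random")
    out$global <- fitOne(seq_len(nrow(Xs)))
    out$clusters <- lapply(seq_len(part@k), function(lab) {
      idx <- which(part@labels == lab)
      if (length(idx) < (opts$minClusterSize %||% 10L))
        list(members = Xs[idx, , drop = FALSE], clf = NULL)
      else list(members = Xs[idx, , drop = FALSE], clf = fitOne(idx))
    })
  }
  out
}

predictSvmModel <- function(model, table) {
  tab <- imputeCohort(table, model$imputeStats)
  Xs <- applyScaler(model$scaler, tab@X)
  callClf <- function(clf, x) {
    if (!is.null(clf$const)) return(clf$const)
    as.character(stats::predict(clf$svm, matrix(x, nrow = 1L)))
  }
  vapply(seq_len(nrow(Xs)), function(i) {
    x <- Xs[i, ]
    clf <- model$global
    if (!is.null(model$clusters)) {
      d <- vapply(model$clusters, function(cl)
        linkageDistance(x, cl$members, model$linkage), 0)
      cand <- model$clusters[[which.min(d)]]$clf
      if (!is.null(cand)) clf <- cand
    }
    callClf(clf, x)
  }, "")
}

stratifiedSplit <- function(y, testFraction, seed) {
  withSeed(seed, {
    for (attempt in 1:100) {
      test <- integer(0)
      for (lv in unique(y)) {
        rows <- which(y == lv)
        nTest <- round(length(rows) * testFraction)
        if (nTest > 0L && nTest < length(rows))
          test <- c(test, sample(rows, nTest))
        else if (nTest >= length(rows))
          test <- c(test, sample(rows, length(rows) - 1L))
      }
      train <- setdiff(seq_along(y), test)
      if (all(unique(y) %in% y[train])) return(sort(test))
    }
  })
  stop("could not draw a split containing every class in training",
       call. = FALSE)
}

#' Repeated stratified holdout evaluation
#'
#' The experimental protocol: for each repeat a stratified random 80/20
#' train/test split is drawn once and shared by every registered method (so
#' paired comparisons are valid); each method is fitted on the training side
#' only and scored by its misclassification rate on the test side. For
#' clustered models, each cluster's tree is additionally evaluated alone on
#' the full test set (rows named \code{<method>.K<j>}).
#'
#' @param table a labeled \code{\linkS4class{CohortTable}}.
#' @param methods list of method objects from \code{\link{nccMethod}} (or any
#'   list with \code{name}/\code{fit}/\code{predict}).
#' @param repeats number of repeats; default 10.
#' @param testFraction held-out fraction; default 0.2.
#' @param seed master seed.
#' @param positive positive class for the pooled confusion metrics.
#' @param clusterBars evaluate single-cluster trees too; default TRUE.
#' @return an \code{\linkS4class{ExperimentResult}}.
#' @export
repeatedHoldout <- function(table, methods, repeats = 10L, testFraction = 0.2,
                            seed = 1L, positive = NULL, clusterBars = TRUE) {
  checkLabeled(table)
  repeats <- assertCount(repeats, "repeats")
  positive <- positive %||% table@schema@positiveClass
  rows <- list(); pooled <- list()
  repSeeds <- vapply(seq_len(repeats), function(r)
    substreamSeed(seed, paste0("split", r)), 0L)
  for (r in seq_len(repeats)) {
    testIdx <- stratifiedSplit(table@y, testFraction, repSeeds[r])
    trainTab <- subsetCohort(table, setdiff(seq_len(nRows(table)), testIdx))
    testTab <- subsetCohort(table, testIdx)
    for (m in methods) {
      fitSeed <- substreamSeed(seed, paste0("fit", r, ":", m$name))
      model <- m$fit(trainTab, fitSeed)
      pred <- m$predict(model, testTab)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m$name, repeatId = r, error = mean(pred != testTab@y))
      pooled[[m$name]] <- rbind(pooled[[m$name]],
                                cbind(truth = testTab@y, pred = pred))
      if (clusterBars && methods::is(model, "NccModel") &&
          length(model@clusters) > 1L) {
        for (cl in model@clusters) {
          tree <- cl$tree %||% model@fallbackTree
          tabImp <- imputeCohort(testTab, model@config$imputeStats)
          predK <- predictTree(tree, applyScaler(model@scaler, tabImp@X))
          nm <- sprintf("%s.K%d", m$name, cl$label)
          rows[[length(rows) + 1L]] <- data.frame(
            method = nm, repeatId = r, error = mean(predK != testTab@y))
          pooled[[nm]] <- rbind(pooled[[nm]],
                                cbind(truth = testTab@y, pred = predK))
        }
      }
    }
  }
  errors <- do.call(rbind, rows)
  metrics <- lapply(pooled, function(pp)
    tryCatch(confusionMetrics(pp[, "truth"], pp[, "pred"], positive),
             error = function(e) NULL))
  new("ExperimentResult", errors = errors,
      metrics = Filter(Negate(is.null), metrics),
      seeds = repSeeds,
      config = list(repeats = repeats, testFraction = testFraction,
                    seed = seed, positive = positive,
                    methods = vapply(methods, `[[`, "", "name")))
}

#' Per-repeat error vector of one method
#' @param result an \code{\linkS4class{ExperimentResult}}.
#' @param method method name.
#' @return numeric vector of per-repeat errors.
#' @export
errorVector <- function(result, method) {
  e <- result@errors
  e$error[e$method == method][order(e$repeatId[e$method == method])]
}

setMethod("show", "ExperimentResult", function(object) {
  agg <- stats::aggregate(error ~ method, object@errors, mean)
  cat(sprintf("ExperimentResult: %d repeats, test fraction %.2f\n",
              object@config$repeats, object@config$testFraction))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-18s mean error %.4f\n", agg$method[i], agg$error[i]))
})

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom, as used
#' to compare per-repeat error distributions of two methods; a paired t-test
#' is available by flag. Wraps \code{\link[stats]{t.test}}.
#'
#' @param a,b numeric vectors (length at least 2 each).
#' @param paired paired test instead; default FALSE.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
welchT <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical-constant samples carry no evidence
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, paired = paired)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Error distributions across a grid of cluster counts
#'
#' Runs \code{\link{repeatedHoldout}} of the nearest consensus clustering
#' classifier for each K in the grid and returns the per-repeat errors in a
#' boxplot-ready long table. A K exceeding the training-set size is skipped
#' with a warning.
#'
#' @param table a labeled \code{\linkS4class{CohortTable}}.
#' @param kValues integer grid; default c(3, 4, 5, 7, 10).
#' @param repeats,testFraction,seed protocol settings.
#' @param ... method options forwarded to \code{\link{fitNearestCC}}.
#' @return data.frame with columns k, repeatId, error.
#' @export
sweepK <- function(table, kValues = c(3L, 4L, 5L, 7L, 10L), repeats = 10L,
                   testFraction = 0.2, seed = 1L, ...) {
  out <- list()
  nTrain <- floor(nRows(table) * (1 - testFraction))
  for (k in kValues) {
    if (k > nTrain) {
      warning("skipping K = ", k, ": larger than the training-set size")
      next
    }
    res <- repeatedHoldout(table, list(nccMethod("nearest-cc", k = k, ...)),
                           repeats = repeats, testFraction = testFraction,
                           seed = seed, clusterBars = FALSE)
    e <- res@errors
    out[[length(out) + 1L]] <- data.frame(k = k, repeatId = e$repeatId,
                                          error = e$error)
  }
  do.call(rbind, out)
}
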