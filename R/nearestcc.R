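# The nearest consensus clustering classifier and its baselines. All three
# share one pipeline: impute -> standardize -> partition the training rows ->
# fit one gain-ratio tree per cluster (plus a fallback tree on all rows) ->
# route a new patient to its linkage-nearest cluster and classify with that
# cluster's tree. They differ only in how the partition is obtained.

#' Linkage distance from a point to a cluster
#'
#' Euclidean distances from \code{x} to every member are reduced by the
#' linkage rule: single = minimum (nearest neighbor), complete = maximum
#' (farthest neighbor), average = mean.
#'
#' @param x standardized feature vector.
#' @param members matrix of standardized member coordinates (nonempty).
#' @param method "single", "complete" or "average".
#' @return nonnegative real.
#' @export
#' @examples
#' m <- rbind(c(0, 0), c(4, 0))
#' linkageDistance(c(1, 0), m, "single")    # 1
#' linkageDistance(c(1, 0), m, "complete")  # 3
#' linkageDistance(c(1, 0), m, "average")   # 2
linkageDistance <- function(x, members,
                            method = c("single", "complete", "average")) {
  method <- match.arg(method)
  members <- as.matrix(members)
  if (!nrow(members)) stop("cluster has no members", call. = FALSE)
  d <- sqrt(rowSums(sweep(members, 2, x)^2))
  switch(method, single = min(d), complete = max(d), average = mean(d))
}

#' Route a standardized point to its nearest cluster
#'
#' Returns the cluster whose linkage distance to \code{x} is smallest, ties
#' breaking toward the lowest cluster label.
#'
#' @param x standardized feature vector.
#' @param model a fitted \code{\linkS4class{NccModel}}.
#' @return integer cluster label (0 when the model has no clusters).
#' @export
routeCluster <- function(x, model) {
  if (!length(model@clusters)) return(0L)
  d <- vapply(model@clusters, function(cl)
    linkageDistance(x, cl$members, model@linkage), 0)
  model@clusters[[which.min(d)]]$label
}

defaultTreeParams <- function() {
  list(minLeaf = 2L, minSplit = 4L, maxDepth = 5, minGainRatio = 0)
}

buildClusterModels <- function(Xs, y, rowIds, partition, minClusterSize,
                               treeParams) {
  lapply(seq_len(partition@k), function(lab) {
    idx <- which(partition@labels == lab)
    if (!length(idx)) return(NULL)
    tree <- if (length(idx) >= minClusterSize) {
      do.call(fitTree, c(list(X = Xs[idx, , drop = FALSE], y = y[idx]),
                         treeParams))
    } else NULL
    list(label = lab, members = Xs[idx, , drop = FALSE],
         rowIds = rowIds[idx], n = length(idx), tree = tree)
  }) -> cls
  Filter(Negate(is.null), cls)
}

assembleModel <- function(train, partition, cc, linkage, minClusterSize,
                          treeParams, config) {
  y <- train@y
  fallback <- do.call(fitTree, c(list(X = cc$Xs, y = y), treeParams))
  clusters <- buildClusterModels(cc$Xs, y, train@rowIds, partition,
                                 minClusterSize, treeParams)
  config$treeParams <- treeParams
  config$minClusterSize <- minClusterSize
  config$imputeStats <- cc$imputeStats
  config$featureNames <- train@schema@featureNames
  config$classLevels <- sort(unique(y))
  new("NccModel", scaler = cc$scaler, clusters = clusters,
      fallbackTree = fallback, linkage = linkage, consensus = partition,
      config = config)
}

checkLabeled <- function(train) {
  if (!length(train@y) || anyNA(train@y))
    stop("training data must be fully labeled", call. = FALSE)
}

#' Fit the nearest consensus clustering classifier
#'
#' Pipeline: impute -> fit scaler -> draw b resamples of the training rows ->
#' K-means each resample on the standardized features (class, time and event
#' columns never enter the feature space) -> accumulate the agreement matrix
#' -> K-means its ratio rows into k consensus clusters -> fit one gain-ratio
#' tree per consensus cluster plus a fallback tree on all rows. Clusters with
#' fewer than \code{minClusterSize} members carry no tree and defer to the
#' fallback at prediction time.
#'
#' @param train a labeled \code{\linkS4class{CohortTable}}.
#' @param k number of consensus clusters; default 3.
#' @param b number of resamples; default 10.
#' @param fraction resample fraction; default 0.8.
#' @param withReplacement bootstrap flag; default FALSE.
#' @param linkage routing linkage; default "single".
#' @param minClusterSize smallest cluster that gets its own tree; default 10.
#' @param treeParams list of \code{\link{fitTree}} arguments; default
#'   minLeaf 2, minSplit 4, maxDepth 5, minGainRatio 0.
#' @param seed master seed; every internal draw uses a named substream.
#' @param baseRestarts,baseInit per-resample K-means settings (default one
#'   random-initialisation run).
#' @return a \code{\linkS4class{NccModel}}.
#' @export
fitNearestCC <- function(train, k = 3L, b = 10L, fraction = 0.8,
                         withReplacement = FALSE, linkage = "single",
                         minClusterSize = 10L,
                         treeParams = defaultTreeParams(), seed = 1L,
                         baseRestarts = 1L, baseInit = "random") {
  checkLabeled(train)
  cc <- consensusCluster(train, k = k, b = b, fraction = fraction,
                         withReplacement = withReplacement, seed = seed,
                         baseRestarts = baseRestarts, baseInit = baseInit)
  assembleModel(train, cc$partition, cc, linkage, minClusterSize, treeParams,
                config = list(method = "nearest-cc", k = k, b = b,
                              fraction = fraction,
                              withReplacement = withReplacement, seed = seed))
}

#' Fit the nearest K-means baseline
#'
#' Identical pipeline to \code{\link{fitNearestCC}} but the partition comes
#' from a single K-means clustering of the full training data: no resampling,
#' no consensus. The K-means substream matches the first resample clustering
#' of \code{fitNearestCC}, so with b = 1 and fraction = 1 the two methods
#' coincide.
#'
#' @inheritParams fitNearestCC
#' @return a \code{\linkS4class{NccModel}}.
#' @export
fitNearestKmeans <- function(train, k = 3L, linkage = "single",
                             minClusterSize = 10L,
                             treeParams = defaultTreeParams(), seed = 1L,
                             baseRestarts = 1L, baseInit = "random") {
  checkLabeled(train)
  imp <- fitImputeStats(train)
  tab <- imputeCohort(train, imp)
  scaler <- fitScaler(tab)
  Xs <- applyScaler(scaler, tab@X)
  part <- lloydKmeans(Xs, k, seed = substreamSeed(seed, "base1"),
                      restarts = baseRestarts, init = baseInit)
  cc <- list(Xs = Xs, scaler = scaler, imputeStats = imp)
  assembleModel(train, part, cc, linkage, minClusterSize, treeParams,
                config = list(method = "nearest-kmeans", k = k, seed = seed))
}

#' Fit the global-tree baseline (no clustering)
#'
#' A single gain-ratio tree on all (standardized) training rows, wrapped in
#' the same model container so the prediction interface is uniform: with no
#' clusters to route to, every patient is classified by the fallback tree.
#'
#' @inheritParams fitNearestCC
#' @return a \code{\linkS4class{NccModel}} with zero clusters.
#' @export
fitGlobalTree <- function(train, treeParams = defaultTreeParams(), seed = 1L) {
  checkLabeled(train)
  imp <- fitImputeStats(train)
  tab <- imputeCohort(train, imp)
  scaler <- fitScaler(tab)
  Xs <- applyScaler(scaler, tab@X)
  part <- new("Partition", itemIds = seq_len(nrow(Xs)),
              labels = rep(1L, nrow(Xs)), k = 1L)
  cc <- list(Xs = Xs, scaler = scaler, imputeStats = imp)
  model <- assembleModel(train, part, cc, "single", minClusterSize = 1L,
                         treeParams = treeParams,
                         config = list(method = "global-tree", k = 1L,
                                       seed = seed))
  model@clusters <- list()  # routing disabled; fallback classifies everyone
  model
}

#' Fit a cluster-then-classify model from an arbitrary partitioner
#'
#' Backbone of the comparison grid: any partitioning function (hierarchical,
#' PAM, ...) can replace K-means, and any classifier trainer can replace the
#' gain-ratio tree, behind the same routing interface.
#'
#' @param train a labeled \code{\linkS4class{CohortTable}}.
#' @param partitionFun function(Xs, k, seed) returning a
#'   \code{\linkS4class{Partition}} of the standardized rows.
#' @inheritParams fitNearestCC
#' @return a \code{\linkS4class{NccModel}}.
#' @export
fitClusterThenTree <- function(train, partitionFun, k = 3L,
                               linkage = "single", minClusterSize = 10L,
                               treeParams = defaultTreeParams(), seed = 1L) {
  checkLabeled(train)
  imp <- fitImputeStats(train)
  tab <- imputeCohort(train, imp)
  scaler <- fitScaler(tab)
  Xs <- applyScaler(scaler, tab@X)
  part <- partitionFun(Xs, k, seed)
  cc <- list(Xs = Xs, scaler = scaler, imputeStats = imp)
  assembleModel(train, part, cc, linkage, minClusterSize, treeParams,
                config = list(method = "cluster-then-tree", k = k, seed = seed))
}

#' Classify patients with a fitted model
#'
#' Each row is imputed with the training statistics, scaled with the training
#' scaler (never refitted), routed to its linkage-nearest cluster, and
#' classified by that cluster's tree; clusters without a tree (or a model
#' without clusters) defer to the fallback tree.
#'
#' @param model a fitted \code{\linkS4class{NccModel}}.
#' @param table a schema-compatible \code{\linkS4class{CohortTable}}.
#' @return character vector of predicted labels.
#' @export
predictNearestCC <- function(model, table) {
  if (!identical(colnames(table@X), model@config$featureNames))
    stop("table features do not match the model's training features",
         call. = FALSE)
  tab <- imputeCohort(table, model@config$imputeStats)
  Xs <- applyScaler(model@scaler, tab@X)
  trees <- lapply(model@clusters, `[[`, "tree")
  labelOf <- vapply(model@clusters, `[[`, 0L, "label")
  vapply(seq_len(nrow(Xs)), function(i) {
    x <- Xs[i, ]
    lab <- routeCluster(x, model)
    tree <- if (lab > 0L) trees[[match(lab, labelOf)]] else NULL
    if (is.null(tree)) tree <- model@fallbackTree
    predictTree(tree, x)
  }, "")
}

#' Consensus partition accessor
#' @param model a fitted \code{\linkS4class{NccModel}}.
#' @return the training-row \code{\linkS4class{Partition}}.
#' @export
consensusOf <- function(model) model@consensus

#' Cluster count accessor
#' @param model a fitted \code{\linkS4class{NccModel}}.
#' @return number of cluster models.
#' @export
clusterCount <- function(model) length(model@clusters)

setMethod("show", "NccModel", function(object) {
  cat(sprintf("NccModel (%s): %d cluster(s), linkage = %s\n",
              object@config$method %||% "?", length(object@clusters),
              object@linkage))
  for (cl in object@clusters)
    cat(sprintf("  cluster %d: %d members, %s\n", cl$label, cl$n,
                if (is.null(cl$tree)) "defers to fallback tree"
                else sprintf("tree depth %d", treeDepth(cl$tree))))
  cat(sprintf("  fallback tree depth %d\n", treeDepth(object@fallbackTree)))
})

treeToPlain <- function(tree) {
  if (is.null(tree)) return(NULL)
  lv <- attr(tree, "classLevels")
  strip <- function(nd) {
    if (nd$leaf) list(leaf = TRUE, counts = as.list(nd$counts), label = nd$label)
    else list(leaf = FALSE, feature = nd$feature, featureName = nd$featureName,
              threshold = nd$threshold, gainRatio = nd$gainRatio,
              left = strip(nd$left), right = strip(nd$right))
  }
  list(classLevels = lv, root = strip(tree))
}

plainToTree <- function(plain) {
  if (is.null(plain)) return(NULL)
  build <- function(nd) {
    if (isTRUE(nd$leaf)) {
      counts <- unlist(nd$counts)
      list(leaf = TRUE, counts = counts, label = nd$label)
    } else {
      list(leaf = FALSE, feature = as.integer(nd$feature),
           featureName = nd$featureName, threshold = nd$threshold,
           gainRatio = nd$gainRatio, left = build(nd$left),
           right = build(nd$right))
    }
  }
  tree <- build(plain$root)
  attr(tree, "classLevels") <- unlist(plain$classLevels)
  tree
}

#' Serialize a fitted model to structured text (JSON)
#'
#' Writes the full model -- config, scaler, cluster members by row id, trees
#' in nested form -- at full numeric precision, so fits are diffable and a
#' reloaded model predicts identically.
#'
#' @param model a \code{\linkS4class{NccModel}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNccModel <- function(model, path) {
  obj <- list(
    format = "ncc-model-1",
    linkage = model@linkage,
    config = model@config,
    scaler = list(center = model@scaler@center, spread = model@scaler@spread,
                  kind = model@scaler@kind),
    consensus = list(itemIds = model@consensus@itemIds,
                     labels = model@consensus@labels, k = model@consensus@k),
    clusters = lapply(model@clusters, function(cl)
      list(label = cl$label, rowIds = cl$rowIds, n = cl$n,
           members = apply(cl$members, 1, function(r) r, simplify = FALSE),
           tree = treeToPlain(cl$tree))),
    fallbackTree = treeToPlain(model@fallbackTree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reload a serialized model
#' @param path path written by \code{\link{writeNccModel}}.
#' @return a \code{\linkS4class{NccModel}}.
#' @export
readNccModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  scaler <- new("Scaler", center = num(obj$scaler$center),
                spread = num(obj$scaler$spread),
                kind = as.character(unlist(obj$scaler$kind)))
  clusters <- lapply(obj$clusters, function(cl) {
    members <- do.call(rbind, lapply(cl$members, num))
    colnames(members) <- as.character(unlist(obj$config$featureNames))
    list(label = as.integer(cl$label), members = members,
         rowIds = as.character(unlist(cl$rowIds)), n = as.integer(cl$n),
         tree = plainToTree(cl$tree))
  })
  cfg <- obj$config
  cfg$imputeStats <- stats::setNames(num(cfg$imputeStats),
                                     as.character(unlist(cfg$featureNames)))
  cfg$featureNames <- as.character(unlist(cfg$featureNames))
  cfg$classLevels <- as.character(unlist(cfg$classLevels))
  cfg$treeParams <- lapply(cfg$treeParams, function(v) unlist(v))
  new("NccModel", scaler = scaler, clusters = clusters,
      fallbackTree = plainToTree(obj$fallbackTree),
      linkage = as.character(obj$linkage),
      consensus = new("Partition",
                      itemIds = as.integer(unlist(obj$consensus$itemIds)),
                      labels = as.integer(unlist(obj$consensus$labels)),
                      k = as.integer(obj$consensus$k)),
      config = cfg)
}
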