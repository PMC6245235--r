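# Lloyd K-means with distance-weighted seeding, written here (rather than
# delegating to stats::kmeans) because the consensus pipeline needs exact
# control of seeding, restarts, empty-cluster repair and tie-breaking under
# named rng substreams; stats::kmeans serves as an oracle in the tests.

sqDistToCenters <- function(X, C) {
  # n x k matrix of squared Euclidean distances
  d <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

kmeansPlusPlusInit <- function(X, k) {
  m <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(m, 1L)
  centers[1L, ] <- X[idx, ]
  if (k > 1L) {
    d2 <- sqDistToCenters(X, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      if (sum(d2) <= 0) idx <- sample.int(m, 1L)
      else idx <- sample.int(m, 1L, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, sqDistToCenters(X, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

lloydOnce <- function(X, k, maxIter, tol, init) {
  m <- nrow(X)
  centers <- switch(init,
    pp = kmeansPlusPlusInit(X, k),
    # random-partition start: centers are the means of a random assignment;
    # reaches fixed points whose basins no data-point seeding enters
    assign = {
      lab <- sample(rep_len(seq_len(k), m))
      do.call(rbind, lapply(seq_len(k), function(j)
        colMeans(X[lab == j, , drop = FALSE])))
    },
    X[sample.int(m, k), , drop = FALSE])
  labels <- integer(m)
  sse <- Inf
  for (it in seq_len(maxIter)) {
    D <- sqDistToCenters(X, centers)
    labels <- max.col(-D, ties.method = "first")  # ties -> lowest cluster index
    # empty-cluster repair: reseed at the point farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(labels))
      if (!length(empty)) break
      cur <- D[cbind(seq_len(m), labels)]
      far <- which.max(cur)
      centers[empty[1L], ] <- X[far, ]
      D[, empty[1L]] <- sqDistToCenters(X, centers[empty[1L], , drop = FALSE])[, 1L]
      labels <- max.col(-D, ties.method = "first")
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    newSse <- sum((X - centers[labels, , drop = FALSE])^2)
    if (is.finite(sse) && sse - newSse <= tol) { sse <- min(sse, newSse); break }
    sse <- newSse
  }
  list(labels = labels, centers = centers, sse = sse)
}

#' Lloyd K-means with restarts
#'
#' Standard Lloyd iteration with distance-weighted ("++"-style) seeding by
#' default, multiple restarts (the restart with the lowest within-cluster sum
#' of squared Euclidean distances wins, first such restart on ties), and
#' empty-cluster repair by reseeding the empty centroid at the point farthest
#' from its current centroid. Nearest-centroid ties break toward the lowest
#' cluster index, so the result is deterministic given the seed.
#'
#' @param points m x d numeric matrix.
#' @param k number of clusters (1 <= k <= m).
#' @param seed integer seed.
#' @param restarts number of random restarts; default 10.
#' @param maxIter maximum Lloyd iterations per restart; default 300.
#' @param tol stop when the SSE improvement falls to this or below; default 1e-6.
#' @param init "pp" (distance-weighted seeding, interleaved with
#'   random-partition starts on even restarts) or "random" (k data points).
#' @return a \code{\linkS4class{Partition}} with attributes \code{sse} and
#'   \code{centers}.
#' @export
lloydKmeans <- function(points, k, seed = 1L, restarts = 10L, maxIter = 300L,
                        tol = 1e-6, init = c("pp", "random")) {
  init <- match.arg(init)
  points <- as.matrix(points)
  m <- nrow(points)
  k <- assertCount(k, "k")
  if (k > m) stop("k cannot exceed the number of points", call. = FALSE)
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      # distance-weighted seeding, interleaved with random-partition starts
      # from the second restart on for wider basin coverage
      thisInit <- if (init == "pp" && r %% 2 == 0) "assign" else init
      fit <- lloydOnce(points, k, maxIter, tol, thisInit)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  out <- new("Partition", itemIds = seq_len(m), labels = as.integer(best$labels),
             k = k)
  attr(out, "sse") <- best$sse
  attr(out, "centers") <- best$centers
  out
}

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d items in %d clusters (sizes %s)\n",
              length(object@itemIds), object@k,
              paste(tabulate(object@labels, object@k), collapse = ", ")))
})

#' Export a partition as a two-column CSV (id, label)
#' @param partition a \code{\linkS4class{Partition}}.
#' @param path output path.
#' @param ids optional character ids to write instead of the item indices.
#' @return invisibly, the path.
#' @export
writePartitionCsv <- function(partition, path, ids = NULL) {
  df <- data.frame(id = ids %||% partition@itemIds, label = partition@labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
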