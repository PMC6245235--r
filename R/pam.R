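#' Partitioning around medoids (BUILD + SWAP)
#'
#' K-medoids clustering in which every cluster center must be a data point
#' (the most centrally located member). BUILD greedily selects the k medoids
#' that most reduce the total distance-to-medoid cost; SWAP then repeatedly
#' applies the best improving (medoid, non-medoid) exchange until none exists
#' or \code{maxSwaps} is reached, so the cost is non-increasing across
#' accepted swaps.
#'
#' @param points m x d numeric matrix.
#' @param k number of clusters.
#' @param seed integer seed (used only to break exact cost ties randomly-free;
#'   the procedure itself is deterministic, the argument is kept for interface
#'   symmetry).
#' @param maxSwaps maximum accepted swaps; default 500.
#' @return a \code{\linkS4class{Partition}} with attributes \code{medoids}
#'   (row indices) and \code{cost}.
#' @export
pamPartition <- function(points, k, seed = 1L, maxSwaps = 500L) {
  points <- as.matrix(points)
  m <- nrow(points)
  k <- assertCount(k, "k")
  if (k > m) stop("k cannot exceed the number of points", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  # BUILD
  medoids <- which.min(colSums(D))[1L]
  while (length(medoids) < k) {
    cur <- apply(D[, medoids, drop = FALSE], 1, min)
    gain <- vapply(seq_len(m), function(cand) {
      if (cand %in% medoids) return(-Inf)
      sum(pmax(cur - D[, cand], 0))
    }, 0)
    medoids <- c(medoids, which.max(gain)[1L])
  }
  cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  cur <- cost(medoids)
  swaps <- 0L
  runSwap <- function() {
    repeat {
      bestDelta <- 0; bestSwap <- NULL
      for (i in seq_along(medoids)) {
        for (h in seq_len(m)) {
          if (h %in% medoids) next
          trial <- medoids; trial[i] <- h
          delta <- cost(trial) - cur
          if (delta < bestDelta - 1e-12) { bestDelta <- delta; bestSwap <- c(i, h) }
        }
      }
      if (is.null(bestSwap) || swaps >= maxSwaps) break
      medoids[bestSwap[1L]] <<- bestSwap[2L]
      cur <<- cur + bestDelta
      swaps <<- swaps + 1L
    }
  }
  # Voronoi re-centering (replace each medoid by its cluster's most central
  # member). Equal-cost re-centerings are taken too: they escape BUILD ties
  # that the pairwise SWAP neighbourhood cannot leave; the outer loop stops
  # as soon as a full SWAP + re-center round no longer changes the medoids.
  recenter <- function() {
    labels <- max.col(-D[, medoids, drop = FALSE], ties.method = "first")
    newMed <- vapply(seq_len(k), function(j) {
      members <- which(labels == j)
      if (!length(members)) return(medoids[j])
      members[which.min(rowSums(D[members, members, drop = FALSE]))]
    }, 0L)
    if (cost(newMed) <= cur + 1e-12 && !setequal(newMed, medoids)) {
      medoids <<- newMed
      cur <<- cost(newMed)
      TRUE
    } else FALSE
  }
  for (round in 1:10) {
    runSwap()
    if (!recenter()) break
  }
  medoids <- sort(medoids)
  labels <- max.col(-D[, medoids, drop = FALSE], ties.method = "first")
  out <- new("Partition", itemIds = seq_len(m), labels = as.integer(labels),
             k = k)
  attr(out, "medoids") <- medoids
  attr(out, "cost") <- cost(medoids)
  out
}

#' Agglomerative (hierarchical) partition
#'
#' Deterministic bottom-up merging of the closest pair of clusters under the
#' chosen linkage until k clusters remain; delegates the dendrogram to
#' \code{\link[stats]{hclust}} and cuts it at k.
#'
#' @param points m x d numeric matrix.
#' @param k number of clusters.
#' @param linkage "single", "complete" or "average".
#' @return a \code{\linkS4class{Partition}}.
#' @export
agglomerativePartition <- function(points, k,
                                   linkage = c("single", "complete", "average")) {
  linkage <- match.arg(linkage)
  points <- as.matrix(points)
  m <- nrow(points)
  k <- assertCount(k, "k")
  if (k > m) stop("k cannot exceed the number of points", call. = FALSE)
  if (k == m) {
    return(new("Partition", itemIds = seq_len(m), labels = seq_len(m), k = k))
  }
  hc <- stats::hclust(stats::dist(points), method = linkage)
  labels <- stats::cutree(hc, k = k)
  new("Partition", itemIds = seq_len(m), labels = as.integer(labels), k = k)
}
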