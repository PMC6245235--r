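#' Draw repeated resamples of item indices
#'
#' The consensus layer clusters repeated resamples of the training rows; by
#' default these are 80\% subsamples without replacement, with a bootstrap
#' (fraction 1 with replacement) available by flag. With \code{fraction = 1}
#' and no replacement every collection is the full index set, deterministically.
#'
#' @param n number of items (must be at least 3).
#' @param fraction resample size as a fraction of n, in (0, 1]; default 0.8.
#' @param withReplacement draw with replacement; default FALSE.
#' @param b number of resamples; default 10.
#' @param seed integer seed.
#' @return list of b integer index vectors, each of length round(fraction * n).
#' @export
resampleIndices <- function(n, fraction = 0.8, withReplacement = FALSE,
                            b = 10L, seed = 1L) {
  n <- assertCount(n, "n")
  if (n < 3L) stop("need at least 3 items to resample", call. = FALSE)
  b <- assertCount(b, "b")
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  size <- round(fraction * n)
  if (size < 2L) stop("resample size must be at least 2", call. = FALSE)
  if (fraction == 1 && !withReplacement)
    return(replicate(b, seq_len(n), simplify = FALSE))
  withSeed(seed, {
    lapply(seq_len(b), function(i)
      sort(sample.int(n, size, replace = withReplacement)))
  })
}

#' Build the agreement matrix over resampled clusterings
#'
#' For every pair of items, counts in how many of the resampled clusterings
#' both items were drawn (\code{coPresent}) and in how many of those they fell
#' in the same cluster (\code{coCluster}); the consensus step uses their
#' ratio, with 0 for pairs never jointly sampled. Duplicated indices in a
#' bootstrap resample count once.
#'
#' @param partitions list of \code{\linkS4class{Partition}}s, one per resample,
#'   each defined exactly on its index collection.
#' @param indexCollections list of integer vectors of cohort indices, matching
#'   \code{partitions}.
#' @param n total item count of the cohort.
#' @return an \code{\linkS4class{AgreementMatrix}}.
#' @export
buildAgreementMatrix <- function(partitions, indexCollections, n) {
  n <- assertCount(n, "n")
  stopifnot(length(partitions) == length(indexCollections))
  b <- length(partitions)
  coC <- matrix(0L, n, n)
  coP <- matrix(0L, n, n)
  for (r in seq_len(b)) {
    idx <- indexCollections[[r]]
    p <- partitions[[r]]
    if (max(idx) > n || min(idx) < 1L)
      stop("index collection refers to items outside the cohort", call. = FALSE)
    if (length(p@labels) != length(idx))
      stop("partition does not cover exactly its index collection", call. = FALSE)
    keep <- !duplicated(idx)
    idx <- idx[keep]
    lab <- p@labels[keep]
    coP[idx, idx] <- coP[idx, idx] + 1L
    same <- outer(lab, lab, "==")
    coC[idx, idx] <- coC[idx, idx] + same
  }
  ratio <- matrix(0, n, n)
  pos <- coP > 0
  ratio[pos] <- coC[pos] / coP[pos]
  new("AgreementMatrix", n = n, b = b, coCluster = coC, coPresent = coP,
      ratio = ratio)
}

setMethod("show", "AgreementMatrix", function(object) {
  off <- object@ratio[upper.tri(object@ratio)]
  cat(sprintf("AgreementMatrix: %d items over %d resamples (mean off-diagonal agreement %.3f)\n",
              object@n, object@b, mean(off)))
})

#' Export / import an agreement matrix as CSV
#'
#' Writes the agreement ratio (or raw co-cluster counts) as an n x n
#' header-indexed CSV for inspection.
#'
#' @param A an \code{\linkS4class{AgreementMatrix}}.
#' @param path file path.
#' @param what "ratio", "coCluster" or "coPresent".
#' @return invisibly, the path.
#' @export
writeAgreementCsv <- function(A, path, what = c("ratio", "coCluster", "coPresent")) {
  what <- match.arg(what)
  m <- slot(A, what)
  dimnames(m) <- list(seq_len(A@n), seq_len(A@n))
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname writeAgreementCsv
#' @return \code{readAgreementCsv}: the numeric matrix stored in the file.
#' @export
readAgreementCsv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dimnames(m) <- NULL
  m
}

#' Extract the consensus partition from an agreement matrix
#'
#' Each item's row of the agreement ratio is taken as its feature vector (its
#' profile of co-clustering evidence against every other item) and Lloyd
#' K-means groups these profiles, rewarding clusters whose members agree
#' highly with each other and penalizing low-agreement groupings.
#'
#' @param A an \code{\linkS4class{AgreementMatrix}}.
#' @param k number of consensus clusters.
#' @param seed integer seed.
#' @param restarts,init passed to \code{\link{lloydKmeans}} (defaults 10, "pp").
#' @return a full-cohort \code{\linkS4class{Partition}}.
#' @export
consensusPartition <- function(A, k, seed = 1L, restarts = 10L, init = "pp") {
  if (k > A@n) stop("k cannot exceed the number of items", call. = FALSE)
  lloydKmeans(A@ratio, k, seed = seed, restarts = restarts, init = init)
}

#' Consensus clustering of a cohort
#'
#' The unsupervised half of the pipeline: standardize the (imputed) features,
#' cluster b resampled subsets with K-means, accumulate the agreement matrix,
#' and extract the consensus partition. Class/time/event columns never enter
#' the feature space.
#'
#' @param table a \code{\linkS4class{CohortTable}}.
#' @param k number of clusters.
#' @param b number of resamples; default 10.
#' @param fraction resample fraction; default 0.8.
#' @param withReplacement bootstrap flag; default FALSE.
#' @param seed master seed; all internal draws use named substreams of it.
#' @param baseRestarts,baseInit settings of the per-resample K-means runs
#'   (default a single random-initialisation run: the consensus layer, not
#'   restarts, is the stabiliser).
#' @param consensusRestarts restarts of the consensus-extraction K-means.
#' @return list with \code{partition} (\code{\linkS4class{Partition}}),
#'   \code{agreement} (\code{\linkS4class{AgreementMatrix}}),
#'   \code{scaler} and \code{Xs} (the standardized feature matrix).
#' @export
consensusCluster <- function(table, k, b = 10L, fraction = 0.8,
                             withReplacement = FALSE, seed = 1L,
                             baseRestarts = 1L, baseInit = "random",
                             consensusRestarts = 10L) {
  imp <- fitImputeStats(table)
  tab <- imputeCohort(table, imp)
  scaler <- fitScaler(tab)
  Xs <- applyScaler(scaler, tab@X)
  n <- nrow(Xs)
  idx <- resampleIndices(n, fraction, withReplacement, b,
                         seed = substreamSeed(seed, "resample"))
  parts <- lapply(seq_len(b), function(r)
    lloydKmeans(Xs[idx[[r]], , drop = FALSE], k,
                seed = substreamSeed(seed, paste0("base", r)),
                restarts = baseRestarts, init = baseInit))
  A <- buildAgreementMatrix(parts, idx, n)
  part <- consensusPartition(A, k, seed = substreamSeed(seed, "consensus"),
                             restarts = consensusRestarts)
  list(partition = part, agreement = A, scaler = scaler, Xs = Xs,
       imputeStats = imp)
}

# optimal injective alignment of q's labels onto p's by maximizing overlap,
# exhaustive over assignments (cluster counts are small)
alignLabels <- function(ct) {
  kp <- nrow(ct); kq <- ncol(ct)
  bestScore <- -1; bestMap <- NULL
  qOrder <- order(-rowSums(t(ct)))  # consider big q-clusters first
  recurse <- function(pos, usedP, map, score) {
    if (pos > kq) {
      if (score > bestScore) { bestScore <<- score; bestMap <<- map }
      return(invisible())
    }
    upper <- score + sum(apply(ct[, qOrder[pos:kq], drop = FALSE], 2, max))
    if (upper <= bestScore) return(invisible())
    q <- qOrder[pos]
    cands <- c(setdiff(order(-ct[, q]), usedP), 0L)  # 0 = leave unmatched
    for (p in cands) {
      map2 <- map; map2[q] <- p
      recurse(pos + 1L, if (p) c(usedP, p) else usedP, map2,
              score + if (p) ct[p, q] else 0)
    }
  }
  recurse(1L, integer(0), integer(kq), 0)
  bestMap
}

#' Chance-corrected agreement between two partitions
#'
#' Cluster labels are nominal, so the labels of \code{q} are first aligned to
#' those of \code{p} by an optimal one-to-one matching on the contingency
#' table (maximum total overlap); Cohen's kappa of the aligned label vectors
#' is then returned. Scores range from -1 (poor) through 0 (chance) to +1
#' (perfect agreement). The partitions need not have the same number of
#' clusters: unmatched clusters keep fresh labels that never agree.
#'
#' @param p,q \code{\linkS4class{Partition}}s over identical item sets.
#' @return a real in [-1, 1].
#' @export
kappaAgreement <- function(p, q) {
  if (!setequal(p@itemIds, q@itemIds) ||
      length(p@itemIds) != length(q@itemIds))
    stop("partitions must cover identical item sets", call. = FALSE)
  ord <- match(p@itemIds, q@itemIds)
  a <- p@labels
  bRaw <- q@labels[ord]
  ct <- as.matrix(table(factor(a, levels = seq_len(p@k)),
                        factor(bRaw, levels = seq_len(q@k))))
  map <- alignLabels(ct)
  nextFree <- p@k
  b <- integer(length(bRaw))
  for (qq in seq_len(q@k)) {
    tgt <- map[qq]
    if (tgt == 0L) { nextFree <- nextFree + 1L; tgt <- nextFree }
    b[bRaw == qq] <- tgt
  }
  lv <- sort(unique(c(a, b)))
  af <- factor(a, levels = lv); bf <- factor(b, levels = lv)
  tt <- table(af, bf)
  n <- sum(tt)
  po <- sum(diag(tt)) / n
  pe <- sum(rowSums(tt) * colSums(tt)) / n^2
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}
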