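# C4.5-style gain-ratio decision trees. Trees are nested lists:
#   leaf : list(leaf = TRUE, counts = named integer, label = character)
#   split: list(leaf = FALSE, feature = integer index, featureName, threshold,
#               left, right)   with the "value <= threshold goes left" rule.
# Binary 0/1 features fall out of the same machinery (single candidate 0.5).

#' Shannon entropy of a label vector, in bits
#' @param labels vector of class labels (at least one).
#' @return nonnegative entropy in bits.
#' @export
#' @examples
#' entropyBits(c("1", "1", "2", "2"))  # 1 bit
entropyBits <- function(labels) {
  if (!length(labels)) stop("entropy of an empty label set is undefined",
                            call. = FALSE)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain ratio of a candidate split
#'
#' gain = H(parent) - sum_i (n_i/n) H(child_i); splitInfo = entropy of the
#' child-size proportions; gainRatio = gain / splitInfo, defined as 0 when
#' splitInfo is 0 (a degenerate one-sided split).
#'
#' @param parent vector of parent labels.
#' @param children list of child label vectors that partition the parent
#'   multiset.
#' @return the gain ratio (a real; in [0, 1] for binary class problems).
#' @export
gainRatio <- function(parent, children) {
  kid <- unlist(lapply(children, as.character), use.names = FALSE)
  if (!identical(sort(as.character(parent)), sort(kid)))
    stop("children must partition the parent label multiset", call. = FALSE)
  n <- length(parent)
  sizes <- lengths(children)
  gain <- entropyBits(parent) -
    sum(vapply(children, function(ch)
      if (length(ch)) length(ch) / n * entropyBits(ch) else 0, 0))
  pr <- sizes[sizes > 0] / n
  splitInfo <- -sum(pr * log2(pr))
  if (splitInfo <= 0) return(0)
  gain / splitInfo
}

# entropy of rows of a count matrix, vectorized; counts: r x L
rowEntropy <- function(counts, totals) {
  p <- counts / totals
  contrib <- p * log2(p)
  contrib[!is.finite(contrib)] <- 0
  -rowSums(contrib)
}

# candidate threshold splits of one feature: thresholds, gains, gain ratios
# (vectorized over all midpoints between consecutive distinct sorted values).
# yInt: integer class codes 1..L.
featureSplitStats <- function(x, yInt, L, minLeaf) {
  m <- length(x)
  ord <- order(x, method = "radix")
  xs <- x[ord]; ys <- yInt[ord]
  cum <- matrix(0, m, L)
  for (l in seq_len(L)) cum[, l] <- cumsum(ys == l)
  cutIdx <- which(xs[-m] < xs[-1])
  cutIdx <- cutIdx[cutIdx >= minLeaf & (m - cutIdx) >= minLeaf]
  if (!length(cutIdx)) return(NULL)
  nL <- cutIdx; nR <- m - cutIdx
  leftCounts <- cum[cutIdx, , drop = FALSE]
  rightCounts <- matrix(cum[m, ], length(cutIdx), L, byrow = TRUE) - leftCounts
  Hp <- rowEntropy(matrix(cum[m, ], 1L, L), m)
  HL <- rowEntropy(leftCounts, nL)
  HR <- rowEntropy(rightCounts, nR)
  gain <- Hp - (nL / m) * HL - (nR / m) * HR
  pl <- nL / m; prr <- nR / m
  splitInfo <- -(pl * log2(pl) + prr * log2(prr))
  ratio <- ifelse(splitInfo > 0, gain / splitInfo, 0)
  list(thresholds = (xs[cutIdx] + xs[cutIdx + 1L]) / 2,
       ratio = ratio, gain = gain)
}

# choose the node's split: among candidates over all features, restrict to
# those whose information gain is at least the average gain of all
# candidates (the C4.5 safeguard against near-degenerate splits whose tiny
# split-info inflates the ratio), then maximize the gain ratio; ties break
# toward the lowest feature index, then the lowest threshold.
chooseSplit <- function(X, yInt, L, minLeaf, gainGuard = TRUE) {
  stats <- lapply(seq_len(ncol(X)), function(j)
    featureSplitStats(X[, j], yInt, L, minLeaf))
  allGains <- unlist(lapply(stats, `[[`, "gain"))
  if (!length(allGains)) return(NULL)
  minGain <- if (gainGuard) mean(allGains) - 1e-12 else -Inf
  best <- NULL
  for (j in seq_along(stats)) {
    st <- stats[[j]]
    ok <- which(st$gain >= minGain)
    if (!length(ok)) next
    b <- ok[which.max(st$ratio[ok])]  # thresholds ascend: ties -> lowest
    if (is.null(best) || st$ratio[b] > best$ratio)
      best <- list(feature = j, threshold = st$thresholds[b],
                   ratio = st$ratio[b], gain = st$gain[b])
  }
  best
}

leafNode <- function(yInt, classLevels) {
  counts <- tabulate(yInt, length(classLevels))
  names(counts) <- classLevels
  # argmax with ties toward the lexicographically smallest label
  ordLex <- order(classLevels)
  lab <- classLevels[ordLex][which.max(counts[ordLex])]
  list(leaf = TRUE, counts = counts, label = lab)
}

growTree <- function(X, yInt, classLevels, depth, params) {
  m <- length(yInt)
  pure <- length(unique(yInt)) == 1L
  if (pure || m < params$minSplit ||
      (!is.infinite(params$maxDepth) && depth >= params$maxDepth))
    return(leafNode(yInt, classLevels))
  L <- length(classLevels)
  best <- chooseSplit(X, yInt, L, params$minLeaf, params$gainGuard)
  if (is.null(best) || best$ratio <= params$minGainRatio)
    return(leafNode(yInt, classLevels))
  goLeft <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature,
       featureName = colnames(X)[best$feature] %||% as.character(best$feature),
       threshold = best$threshold, gainRatio = best$ratio,
       left = growTree(X[goLeft, , drop = FALSE], yInt[goLeft], classLevels,
                       depth + 1L, params),
       right = growTree(X[!goLeft, , drop = FALSE], yInt[!goLeft], classLevels,
                        depth + 1L, params))
}

#' Fit a gain-ratio decision tree
#'
#' Greedy recursive partitioning in the C4.5 spirit: at every node each
#' feature is scanned over the midpoints between consecutive distinct sorted
#' values (a binary 0/1 feature thus offers the single 0.5 threshold) and the
#' split with the largest information gain ratio is taken, ties breaking
#' toward the lowest feature index and then the lowest threshold. Following
#' C4.5's safeguard, only candidates whose plain information gain reaches
#' the average gain over all of the node's candidates compete on the ratio
#' (without this, near-degenerate splits with tiny split-info dominate);
#' \code{gainGuard = FALSE} disables it. Growth
#' stops at pure nodes, nodes smaller than \code{minSplit}, at
#' \code{maxDepth}, or when the best gain ratio does not exceed
#' \code{minGainRatio}. No post-pruning is applied.
#'
#' @param X m x d numeric matrix.
#' @param y class labels, length m.
#' @param minLeaf smallest admissible child; default 2.
#' @param minSplit smallest node still considered for splitting; default 4.
#' @param maxDepth maximum depth (root = 0); default Inf.
#' @param minGainRatio stop when the best ratio is at or below this; default 0.
#' @param gainGuard apply C4.5's average-gain admissibility test; default TRUE.
#' @return a tree (nested list) with attribute \code{classLevels}.
#' @export
fitTree <- function(X, y, minLeaf = 2L, minSplit = 4L, maxDepth = Inf,
                    minGainRatio = 0, gainGuard = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("at least one feature is required", call. = FALSE)
  if (nrow(X) < 1L || length(y) != nrow(X))
    stop("y must label every row of X", call. = FALSE)
  classLevels <- sort(unique(as.character(y)))
  yInt <- match(as.character(y), classLevels)
  params <- list(minLeaf = minLeaf, minSplit = minSplit, maxDepth = maxDepth,
                 minGainRatio = minGainRatio, gainGuard = gainGuard)
  tree <- growTree(X, yInt, classLevels, 0L, params)
  attr(tree, "classLevels") <- classLevels
  tree
}

#' Predict with a fitted tree
#'
#' Deterministic descent; a value equal to a node's threshold goes left
#' (the <= convention).
#'
#' @param tree a tree from \code{\link{fitTree}}.
#' @param X a feature vector or matrix of rows to classify.
#' @return character label(s).
#' @export
predictTree <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  apply(X, 1L, function(x) {
    node <- tree
    while (!node$leaf)
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    node$label
  })
}

#' Render a tree as indented text
#' @param tree a tree from \code{\link{fitTree}}.
#' @param indent internal.
#' @return character vector of lines, invisibly printed.
#' @export
formatTree <- function(tree, indent = "") {
  if (tree$leaf) {
    return(sprintf("%s=> %s (%s)", indent, tree$label,
                   paste(names(tree$counts), tree$counts, sep = ":",
                         collapse = " ")))
  }
  c(sprintf("%s%s <= %.4g", indent, tree$featureName, tree$threshold),
    formatTree(tree$left, paste0(indent, "  ")),
    sprintf("%s%s >  %.4g", indent, tree$featureName, tree$threshold),
    formatTree(tree$right, paste0(indent, "  ")))
}

treeDepth <- function(tree) {
  if (tree$leaf) 0L else 1L + max(treeDepth(tree$left), treeDepth(tree$right))
}
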