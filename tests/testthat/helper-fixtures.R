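# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (double loops, exhaustive enumeration) and never reuse
# package internals.

tinySchema <- function(withSurvival = FALSE) {
  cohortSchema(c("a", "b"), c("continuous", "binary"), classColumn = "cls",
               timeColumn = if (withSurvival) "t" else NULL,
               eventColumn = if (withSurvival) "e" else NULL)
}

randomCohort <- function(n, d = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  sc <- cohortSchema(colnames(X), "continuous", classColumn = "cls")
  cohortTable(X, sc, y = sample(c("1", "2"), n, replace = TRUE))
}

# brute-force pairwise agreement counts
oracleAgreement <- function(partitions, collections, n) {
  coC <- matrix(0L, n, n); coP <- matrix(0L, n, n)
  for (r in seq_along(partitions)) {
    idx <- collections[[r]]
    keep <- !duplicated(idx)
    idx <- idx[keep]; lab <- partitions[[r]]@labels[keep]
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      coP[idx[i], idx[j]] <- coP[idx[i], idx[j]] + 1L
      if (lab[i] == lab[j]) coC[idx[i], idx[j]] <- coC[idx[i], idx[j]] + 1L
    }
  }
  list(coCluster = coC, coPresent = coP)
}

# exhaustive minimum SSE over all 2-cluster bipartitions
oracleBestSse2 <- function(X) {
  m <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(m - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
    if (!any(grp) || all(grp)) next
    sse <- 0
    for (g in list(grp, !grp)) {
      Y <- X[g, , drop = FALSE]
      sse <- sse + sum(sweep(Y, 2, colMeans(Y))^2)
    }
    best <- min(best, sse)
  }
  best
}

# brute-force PAM optimum over all medoid subsets
oraclePamCost <- function(X, k) {
  D <- as.matrix(dist(X))
  best <- Inf
  for (med in utils::combn(nrow(X), k, simplify = FALSE))
    best <- min(best, sum(apply(D[, med, drop = FALSE], 1, min)))
  best
}

# independent entropy / gain-ratio arithmetic (sum-based, not cumsum-based)
oracleEntropy <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

oracleGainRatio <- function(parent, left, right) {
  n <- length(parent)
  gain <- oracleEntropy(parent) -
    length(left) / n * oracleEntropy(left) -
    length(right) / n * oracleEntropy(right)
  pr <- c(length(left), length(right)) / n
  pr <- pr[pr > 0]
  si <- -sum(pr * log2(pr))
  if (si <= 0) return(list(gain = gain, ratio = 0))
  list(gain = gain, ratio = gain / si)
}

# exhaustive root-split search mirroring the C4.5 admissibility rule:
# gains at least the mean candidate gain compete on the ratio; ties ->
# lowest feature, then lowest threshold
oracleRootSplit <- function(X, y, minLeaf = 2, gainGuard = TRUE) {
  cands <- list()
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      left <- y[X[, j] <= thr]; right <- y[X[, j] > thr]
      if (length(left) < minLeaf || length(right) < minLeaf) next
      gr <- oracleGainRatio(y, left, right)
      cands[[length(cands) + 1L]] <-
        list(feature = j, threshold = thr, gain = gr$gain, ratio = gr$ratio)
    }
  }
  if (!length(cands)) return(NULL)
  gains <- vapply(cands, `[[`, 0, "gain")
  keep <- if (gainGuard) gains >= mean(gains) - 1e-12 else rep(TRUE, length(gains))
  cands <- cands[keep]
  ratios <- vapply(cands, `[[`, 0, "ratio")
  cands[[which.max(ratios)]]  # candidates are ordered by (feature, threshold)
}

# plain product-limit arithmetic via survival::survfit
oracleKm <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sm <- summary(fit)
  data.frame(time = sm$time, surv = sm$surv)[sm$n.event > 0, ]
}

adjRand <- function(a, b) mclust::adjustedRandIndex(a, b)
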