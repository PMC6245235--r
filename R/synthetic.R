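# Planted-subgroup cohort generator. Emulates the schema of a systemic-
# sclerosis registry -- continuous labs (Hb, Cr, FVC, DLCO, age at onset) and
# binary autoantibody flags -- with g latent subgroups that differ in their
# feature distributions, in the orientation of the rule linking features to
# the binary outcome class, and in their event hazard. The contradictory
# class rules are the minimal structure under which a single global
# classifier is handicapped while per-cluster classifiers are not.

#' Construct a synthetic cohort specification
#'
#' See \code{\linkS4class{SyntheticSpec}} for the meaning of each field;
#' \code{\link{defaultSscLikeSpec}} builds the standard study conditions.
#'
#' @param n,g,weights cohort size, subgroup count, mixing weights.
#' @param contNames,contMeans,contSds continuous feature names / base means / sds.
#' @param contOffsets g x d_c subgroup mean offsets in sd units.
#' @param binNames,binBase,binOffsets binary feature names, base rates, and
#'   g x d_b probability offsets.
#' @param separation scalar multiplier on between-subgroup spacing.
#' @param classRules list of g \code{list(feature, threshold, orientation)}.
#' @param labelNoise flip probability in [0, 0.5).
#' @param hazards per-subgroup exponential event rates (per month).
#' @param censorHorizon uniform censoring horizon (months).
#' @return a validated \code{\linkS4class{SyntheticSpec}}.
#' @export
syntheticSpec <- function(n, g, weights, contNames, contMeans, contSds,
                          contOffsets, binNames, binBase, binOffsets,
                          separation, classRules, labelNoise, hazards,
                          censorHorizon) {
  if (is.null(dim(contSds)))
    contSds <- matrix(contSds, g, length(contNames), byrow = TRUE)
  new("SyntheticSpec", n = as.integer(n), g = as.integer(g),
      weights = weights, contNames = contNames, contMeans = contMeans,
      contSds = as.matrix(contSds), contOffsets = as.matrix(contOffsets),
      binNames = binNames, binBase = binBase,
      binOffsets = as.matrix(binOffsets), separation = separation,
      classRules = classRules, labelNoise = labelNoise, hazards = hazards,
      censorHorizon = censorHorizon)
}

#' The default SSc-like study conditions
#'
#' Three latent subgroups (weights 30/40/30) over five continuous labs and
#' eight antibody flags, built so that the cohort has exactly the structure
#' the method assumes and its baselines lack:
#' \itemize{
#' \item subgroups 1 and 3 are compact and sit 0.78 x \code{separation}
#'   pooled sds apart along the fully oblique (1,1,1,1) direction over
#'   (Hb, Cr, FVC, age); subgroup 2 is \code{separation} from both and
#'   elongated (3.5x sd) along DLCO. Euclidean routing separates the
#'   subgroups cleanly, but every pairwise center difference is oblique, so
#'   any single axis-aligned split -- the only move a decision tree has --
#'   leaks a large fraction of the neighbouring subgroup. Above the default
#'   separation the pair spacing relaxes to equidistant (and the elongation
#'   stops growing), so that larger separation genuinely means easier
#'   recovery; at separation 0 the subgroups are fully exchangeable;
#' \item the elongated subgroup is the geometry a single K-means run handles
#'   worst: depending on its random start it either respects subgroup 2 or
#'   splits it and merges subgroups 1 and 3, so single runs are unstable
#'   (roughly four in ten fail) while the consensus over ten resampled runs
#'   integrates the disagreeing solutions and recovers the subgroups;
#' \item the class rules contradict across subgroups: subgroup 1 is
#'   class "1" when DLCO is high (rate ~0.47), subgroup 3 when DLCO is low
#'   (rate ~0.37, the opposite orientation), and subgroup 2 follows its ACA
#'   antibody instead. No global rule fits the pooled cohort, and a model
#'   that merges subgroups 1 and 3 is nearly blind on the merged mass: the
#'   DLCO signal cancels between the opposite orientations, and the oblique
#'   geometry denies its internal splits a clean re-separation. The
#'   threshold offset between the two rules tilts the merged class balance,
#'   which is what keeps a (majority-capable) global tree strictly ahead of
#'   every single-cluster tree;
#' \item antibody rates drift from their base rates proportionally to
#'   \code{separation} (at separation 0 the subgroups are statistically
#'   identical, elongation included);
#' \item event hazards are ordered (0.020, 0.010, 0.005 per month) so the
#'   subgroup survival curves separate, with uniform censoring on 0..180
#'   months.
#' }
#'
#' @param n cohort size; default 600.
#' @param separation between-subgroup spacing in pooled sds; default 5.
#' @param labelNoise class-flip probability; default 0.05.
#' @return a \code{\linkS4class{SyntheticSpec}}.
#' @export
defaultSscLikeSpec <- function(n = 600L, separation = 5, labelNoise = 0.05) {
  contNames <- c("Hb", "Cr", "FVC", "DLCO", "age")
  contMeans <- c(Hb = 12.6, Cr = 90, FVC = 89, DLCO = 64, age = 49)
  baseSd <- c(Hb = 1.2, Cr = 15, FVC = 18, DLCO = 12, age = 12)
  contSds <- rbind(baseSd, baseSd, baseSd)
  # subgroup 2 is elongated along DLCO; the factor grows with separation
  # (so that at separation 0 the subgroups are fully exchangeable) and is
  # capped at its value for the default spacing
  contSds[2, "DLCO"] <- (1 + 0.5 * min(separation, 5)) * baseSd["DLCO"]
  # rows = subgroups; offsets oblique over (Hb, Cr, FVC, age). The
  # contradictory pair (subgroups 1 and 3) sits pairFactor x separation
  # apart along the fully oblique (1,1,1,1) direction -- per-axis gaps low
  # enough that no single axis-aligned split separates the pair cleanly --
  # while the elongated subgroup 2 is `separation` from both. At the
  # default spacing the pair factor is 0.78, close enough that a single
  # K-means run that misses one pair member merges it decisively into the
  # other; it relaxes to equidistant (1.0) above the default separation,
  # so that wide separation genuinely means easy recovery.
  pairFactor <- min(1, 0.78 + 0.11 * max(0, separation - 5))
  u3 <- rep(pairFactor / 2, 4)
  qPerp <- c(0.5, -0.5, 0.5, -0.5)
  u2 <- u3 / 2 + sqrt(1 - pairFactor^2 / 4) * qPerp
  u <- rbind(rep(0, 5), c(u2[1:3], 0, u2[4]), c(u3[1:3], 0, u3[4]))
  binNames <- c("ACA", "ATA", "ARA", "U3RNP", "NRNP", "PMSCL", "RO", "ANA")
  binBase <- c(ACA = 0.28, ATA = 0.20, ARA = 0.10, U3RNP = 0.04,
               NRNP = 0.07, PMSCL = 0.05, RO = 0.06, ANA = 0.15)
  binOff <- rbind(c(-0.02, -0.05,  0.05, 0,     0,    0,    0,  0.05),
                  c( 0.037, 0.05,  0,    0.02,  0,    0,    0, -0.05),
                  c(-0.02,  0,    -0.05, -0.02, 0.03, 0,    0,  0)) / 6
  t1 <- unname(contMeans["DLCO"] + 0.075 * baseSd["DLCO"])
  t3 <- unname(contMeans["DLCO"] - 0.33 * baseSd["DLCO"])
  rules <- list(
    list(feature = "DLCO", threshold = t1, orientation = ">"),  # rate ~0.47
    list(feature = "ACA",  threshold = 0.5, orientation = ">"), # own antibody
    list(feature = "DLCO", threshold = t3, orientation = "<"))  # rate ~0.37
  syntheticSpec(n = n, g = 3L, weights = c(0.3, 0.4, 0.3),
                contNames = contNames, contMeans = unname(contMeans),
                contSds = unname(contSds), contOffsets = u,
                binNames = binNames, binBase = unname(binBase),
                binOffsets = binOff, separation = separation,
                classRules = rules, labelNoise = labelNoise,
                hazards = c(0.020, 0.010, 0.005), censorHorizon = 180)
}

#' Schema of a synthetic cohort
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @return the matching \code{\linkS4class{CohortSchema}} (class column
#'   "cls", survival columns "time"/"event").
#' @export
syntheticSchema <- function(spec) {
  cohortSchema(
    featureNames = c(spec@contNames, spec@binNames),
    featureKinds = c(rep("continuous", length(spec@contNames)),
                     rep("binary", length(spec@binNames))),
    classColumn = "cls", timeColumn = "time", eventColumn = "event",
    positiveClass = "1")
}

#' Generate a synthetic cohort with planted subgroups
#'
#' Each patient draws a subgroup from the mixing weights; continuous labs are
#' Gaussian around the subgroup mean (base mean + separation-scaled offset),
#' antibodies are Bernoulli with the subgroup's rates, the class follows the
#' subgroup's own threshold rule (flipped with probability
#' \code{labelNoise}), and the event time is exponential with the subgroup's
#' hazard, censored at an independent uniform horizon. With
#' \code{classFrom = "survival"} the class is instead re-derived from the
#' survival columns via \code{\link{labelTimeToEvent}} and the
#' censored-before-threshold rows are dropped.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param classFrom "rule" (default) or "survival".
#' @param thresholdMonths threshold for \code{classFrom = "survival"};
#'   default 60.
#' @return list with \code{table} (a \code{\linkS4class{CohortTable}}) and
#'   \code{subgroup} (the true integer subgroup of each retained row).
#' @export
generateCohort <- function(spec, seed = 1L, classFrom = c("rule", "survival"),
                           thresholdMonths = 60) {
  classFrom <- match.arg(classFrom)
  validObject(spec)
  n <- spec@n; g <- spec@g
  dc <- length(spec@contNames); db <- length(spec@binNames)
  withSeed(seed, {
    sub <- sample.int(g, n, replace = TRUE, prob = spec@weights)
    # offsets are expressed in pooled within-subgroup sd units
    refSd <- sqrt(colSums(spec@weights * spec@contSds^2))
    Xc <- matrix(0, n, dc)
    for (j in seq_len(dc)) {
      mu <- spec@contMeans[j] +
        spec@separation * spec@contOffsets[sub, j] * refSd[j]
      Xc[, j] <- stats::rnorm(n, mu, spec@contSds[sub, j])
    }
    Xb <- matrix(0, n, db)
    for (j in seq_len(db)) {
      p <- spec@binBase[j] + spec@separation * spec@binOffsets[sub, j]
      p <- pmin(pmax(p, 0.01), 0.99)
      Xb[, j] <- stats::rbinom(n, 1L, p)
    }
    Xall <- cbind(Xc, Xb)
    colnames(Xall) <- c(spec@contNames, spec@binNames)
    y <- character(n)
    for (i in seq_len(n)) {
      rule <- spec@classRules[[sub[i]]]
      v <- Xall[i, rule$feature]
      hit <- if (rule$orientation == ">") v > rule$threshold else v < rule$threshold
      y[i] <- if (hit) "1" else "2"
    }
    flip <- stats::runif(n) < spec@labelNoise
    y[flip] <- ifelse(y[flip] == "1", "2", "1")
    evTime <- stats::rexp(n, rate = spec@hazards[sub])
    cens <- stats::runif(n, 0, spec@censorHorizon)
    time <- pmin(evTime, cens)
    event <- as.integer(evTime <= cens)
  })
  X <- cbind(Xc, Xb)
  colnames(X) <- c(spec@contNames, spec@binNames)
  tab <- cohortTable(X, syntheticSchema(spec), y = y, time = time,
                     event = event)
  if (classFrom == "survival") {
    lt <- labelTimeToEvent(tab, thresholdMonths)
    tab@y <- lt$labels
    tab <- subsetCohort(tab, lt$included)
    sub <- sub[lt$included]
  }
  list(table = tab, subgroup = sub)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: n = %d, %d subgroups (weights %s), separation %.3g\n",
              object@n, object@g,
              paste(format(object@weights), collapse = "/"),
              object@separation))
  cat(sprintf("  %d continuous + %d binary features; label noise %.2f; hazards %s /month\n",
              length(object@contNames), length(object@binNames),
              object@labelNoise, paste(format(object@hazards), collapse = ", ")))
})
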