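#' @import methods
NULL

#' Cohort schema
#'
#' Describes the columns of a delimited cohort file: which columns are
#' features (and whether each is continuous or binary), which column holds the
#' class label, and which hold the time-to-event and event-status information.
#' Binary features may carry a recode map translating dataset-specific codes
#' (e.g. "1"/"2") to 0/1.
#'
#' @slot featureNames character vector of feature column names (unique).
#' @slot featureKinds character vector, one of \code{"continuous"} or
#'   \code{"binary"} per feature.
#' @slot classColumn length-0 or length-1 character; the class label column.
#' @slot timeColumn length-0 or length-1 character; months to event.
#' @slot eventColumn length-0 or length-1 character; 1 = event occurred,
#'   0 = censored.
#' @slot positiveClass label treated as "event before threshold" in metrics.
#' @slot recodeMaps named list; per-feature named numeric vectors mapping raw
#'   codes to stored values, e.g. \code{list(gender = c("1" = 0, "2" = 1))}.
#' @export
setClass("CohortSchema",
  representation(
    featureNames = "character",
    featureKinds = "character",
    classColumn  = "character",
    timeColumn   = "character",
    eventColumn  = "character",
    positiveClass = "character",
    recodeMaps   = "list"
  ),
  prototype(classColumn = character(0), timeColumn = character(0),
            eventColumn = character(0), positiveClass = "1",
            recodeMaps = list())
)

setValidity("CohortSchema", function(object) {
  msg <- character(0)
  fn <- object@featureNames
  if (anyDuplicated(fn)) msg <- c(msg, "feature names must be unique")
  if (length(object@featureKinds) != length(fn))
    msg <- c(msg, "featureKinds must match featureNames in length")
  if (!all(object@featureKinds %in% c("continuous", "binary")))
    msg <- c(msg, "featureKinds must be 'continuous' or 'binary'")
  special <- c(object@classColumn, object@timeColumn, object@eventColumn)
  if (any(fn %in% special))
    msg <- c(msg, "feature names must be disjoint from class/time/event columns")
  if (length(object@classColumn) > 1 || length(object@timeColumn) > 1 ||
      length(object@eventColumn) > 1)
    msg <- c(msg, "class/time/event columns must each be a single name or absent")
  if (length(object@recodeMaps) &&
      !all(names(object@recodeMaps) %in% fn))
    msg <- c(msg, "recodeMaps names must be feature names")
  if (length(msg)) msg else TRUE
})

#' Patient cohort table
#'
#' A feature matrix with optional class labels and right-censored survival
#' columns, plus the schema it was read under. The feature matrix keeps
#' continuous values in native units and binary features as 0/1; missing
#' values are allowed at ingest and removed by \code{\link{imputeCohort}}.
#'
#' @slot X numeric matrix, patients in rows, features in columns.
#' @slot y character vector of class labels (NA = absent), length 0 or nrow(X).
#' @slot time numeric months to event/censoring, length 0 or nrow(X).
#' @slot event integer 0/1 event indicator, length 0 or nrow(X).
#' @slot rowIds character, stable row identifiers.
#' @slot schema a \code{\linkS4class{CohortSchema}}.
#' @export
setClass("CohortTable",
  representation(
    X = "matrix", y = "character", time = "numeric",
    event = "integer", rowIds = "character", schema = "CohortSchema"
  )
)

setValidity("CohortTable", function(object) {
  msg <- character(0)
  n <- nrow(object@X)
  if (!is.numeric(object@X)) msg <- c(msg, "X must be numeric")
  if (length(object@rowIds) != n) msg <- c(msg, "rowIds must have one id per row")
  if (anyDuplicated(object@rowIds)) msg <- c(msg, "rowIds must be unique")
  for (nm in c("y", "time", "event")) {
    v <- slot(object, nm)
    if (length(v) && length(v) != n)
      msg <- c(msg, sprintf("%s must have length 0 or n_rows", nm))
  }
  if (length(object@time) && any(object@time < 0, na.rm = TRUE))
    msg <- c(msg, "time must be nonnegative")
  if (length(object@event) && !all(object@event %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "event must be 0/1")
  if (!identical(colnames(object@X), object@schema@featureNames))
    msg <- c(msg, "X columns must equal schema featureNames")
  if (length(msg)) msg else TRUE
})

#' Feature scaler
#'
#' Per-feature center/spread fitted on training rows only. Continuous features
#' are z-scored (sample standard deviation, divisor n-1); constant features get
#' spread 1 so they map to 0; binary features pass through unchanged.
#'
#' @slot center numeric per-feature center.
#' @slot spread positive numeric per-feature spread.
#' @slot kind character per-feature kind flag.
#' @export
setClass("Scaler",
  representation(center = "numeric", spread = "numeric", kind = "character"))

setValidity("Scaler", function(object) {
  msg <- character(0)
  d <- length(object@center)
  if (length(object@spread) != d || length(object@kind) != d)
    msg <- c(msg, "center, spread and kind must have equal length")
  if (any(object@spread <= 0)) msg <- c(msg, "spread must be positive")
  if (length(msg)) msg else TRUE
})

#' Cluster partition
#'
#' An assignment of item indices to cluster labels \code{1..k} (exhaustive and
#' disjoint over the covered items).
#'
#' @slot itemIds integer indices of the items covered.
#' @slot labels integer cluster labels in 1..k, one per item.
#' @slot k integer number of clusters.
#' @export
setClass("Partition",
  representation(itemIds = "integer", labels = "integer", k = "integer"))

setValidity("Partition", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@itemIds))
    msg <- c(msg, "labels must cover every item exactly once")
  if (anyDuplicated(object@itemIds)) msg <- c(msg, "itemIds must be unique")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Pairwise co-clustering evidence over resampled clusterings
#'
#' For each pair of items, \code{coCluster} counts the resampled clusterings
#' that placed both in the same cluster and \code{coPresent} counts the
#' resamples where both were drawn at all; \code{ratio} is their quotient
#' (0 where a pair was never jointly sampled). The consensus step clusters the
#' rows of \code{ratio}.
#'
#' @slot n integer item count.
#' @slot b integer number of resamples.
#' @slot coCluster n x n integer matrix of same-cluster counts.
#' @slot coPresent n x n integer matrix of joint-presence counts.
#' @slot ratio n x n numeric matrix in [0, 1].
#' @export
setClass("AgreementMatrix",
  representation(n = "integer", b = "integer", coCluster = "matrix",
                 coPresent = "matrix", ratio = "matrix"))

setValidity("AgreementMatrix", function(object) {
  msg <- character(0)
  n <- object@n
  for (nm in c("coCluster", "coPresent", "ratio")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) msg <- c(msg, sprintf("%s must be n x n", nm))
    else if (!isTRUE(all.equal(m, t(m), tolerance = 0)))
      msg <- c(msg, sprintf("%s must be symmetric", nm))
  }
  if (any(object@coCluster > object@coPresent))
    msg <- c(msg, "coCluster cannot exceed coPresent")
  if (any(object@coPresent > object@b))
    msg <- c(msg, "coPresent cannot exceed the number of resamples")
  if (any(object@coCluster < 0) || any(object@coPresent < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (any(object@ratio < 0) || any(object@ratio > 1))
    msg <- c(msg, "ratio must lie in [0, 1]")
  ii <- which(diag(object@coPresent) > 0)
  if (length(ii) && any(abs(diag(object@ratio)[ii] - 1) > 1e-12))
    msg <- c(msg, "ratio diagonal must be 1 for items present in any resample")
  if (length(msg)) msg else TRUE
})

#' Fitted nearest consensus clustering model
#'
#' The complete ensemble produced by \code{\link{fitNearestCC}} and its
#' baseline variants: the training scaler and imputation statistics, the
#' consensus clusters (with member coordinates in standardized feature space
#' and one gain-ratio tree each), a fallback tree trained on all training
#' rows, the linkage method used to route new patients, and a config snapshot
#' sufficient to re-fit identically.
#'
#' @slot scaler the training \code{\linkS4class{Scaler}}.
#' @slot clusters list of cluster models; each a list with elements
#'   \code{label}, \code{members} (standardized coordinate matrix),
#'   \code{rowIds}, \code{n}, and \code{tree} (NULL when the cluster is
#'   smaller than \code{minClusterSize}).
#' @slot fallbackTree gain-ratio tree fitted on all training rows.
#' @slot linkage one of "single", "complete", "average".
#' @slot consensus the consensus \code{\linkS4class{Partition}} of the
#'   training rows (k = 1 partition for the global-tree baseline).
#' @slot config list: k, b, fraction, seeds, tree parameters, imputation
#'   statistics, feature names.
#' @export
setClass("NccModel",
  representation(scaler = "Scaler", clusters = "list", fallbackTree = "list",
                 linkage = "character", consensus = "Partition",
                 config = "list"))

setValidity("NccModel", function(object) {
  msg <- character(0)
  if (!object@linkage %in% c("single", "complete", "average"))
    msg <- c(msg, "linkage must be single, complete or average")
  ids <- unlist(lapply(object@clusters, `[[`, "rowIds"))
  if (length(object@clusters)) {
    if (anyDuplicated(ids))
      msg <- c(msg, "cluster member sets must be disjoint")
    sizes <- vapply(object@clusters, `[[`, 0L, "n")
    if (any(sizes < 1L)) msg <- c(msg, "clusters must be nonempty")
  }
  if (length(msg)) msg else TRUE
})

#' Binary confusion-matrix metrics
#'
#' Counts and derived rates for a binary classification outcome. Rates with a
#' zero denominator are reported as NA, never as 0.
#'
#' @slot tp,fp,tn,fn integer counts.
#' @slot sensitivity,specificity,precision,recall,accuracy,errorRate numeric
#'   in [0, 1] or NA when undefined.
#' @export
setClass("ConfusionMetrics",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
                 sensitivity = "numeric", specificity = "numeric",
                 precision = "numeric", recall = "numeric",
                 accuracy = "numeric", errorRate = "numeric"))

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over the distinct event times: at each event time
#' the curve steps down by the factor (1 - d_i / n_i); censored observations
#' leave the risk set without a step.
#'
#' @slot time numeric ascending distinct event times (months).
#' @slot nRisk integer number at risk just before each event time.
#' @slot nEvent integer number of events at each event time.
#' @slot surv numeric survival probability just after each event time.
#' @export
setClass("KMCurve",
  representation(time = "numeric", nRisk = "integer", nEvent = "integer",
                 surv = "numeric"))

setValidity("KMCurve", function(object) {
  msg <- character(0)
  k <- length(object@time)
  if (length(object@nRisk) != k || length(object@nEvent) != k ||
      length(object@surv) != k)
    msg <- c(msg, "time, nRisk, nEvent, surv must have equal length")
  if (k > 1) {
    if (any(diff(object@time) <= 0)) msg <- c(msg, "times must be ascending")
    if (any(diff(object@surv) > 1e-12)) msg <- c(msg, "survival must be non-increasing")
    if (any(diff(object@nRisk) >= 0)) msg <- c(msg, "at-risk counts must be strictly decreasing")
  }
  if (k && (any(object@surv < -1e-12) || any(object@surv > 1 + 1e-12)))
    msg <- c(msg, "survival must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Repeated-holdout experiment result
#'
#' Per-method, per-repeat misclassification rates under shared train/test
#' splits, plus confusion metrics pooled over the repeats.
#'
#' @slot errors data.frame with columns method, repeatId, error.
#' @slot metrics named list of \code{\linkS4class{ConfusionMetrics}}, one per
#'   method, pooled over repeats.
#' @slot seeds integer seeds used per repeat.
#' @slot config list of protocol settings.
#' @export
setClass("ExperimentResult",
  representation(errors = "data.frame", metrics = "list",
                 seeds = "integer", config = "list"))

#' Synthetic cohort specification
#'
#' Parameters of the planted-subgroup generator: a Gaussian mixture over the
#' continuous labs with subgroup mean offsets scaled by \code{separation},
#' per-subgroup Bernoulli probabilities for the binary antibody flags (also
#' pulled toward a common base rate as separation shrinks), one class rule per
#' subgroup (a threshold on one feature, with orientation allowed to flip
#' across subgroups so no single global rule is consistent), label noise, and
#' subgroup-specific exponential event hazards with uniform censoring.
#'
#' @slot n cohort size.
#' @slot g number of subgroups.
#' @slot weights mixing weights (sum to 1).
#' @slot contNames,contMeans base names and means of the continuous features.
#' @slot contSds g x d_c matrix of per-subgroup standard deviations (unequal
#'   rows make a subgroup elongated along some lab axes, the geometry a
#'   single K-means run handles worst).
#' @slot contOffsets g x d_c matrix of subgroup mean offsets in pooled-sd
#'   units, multiplied by \code{separation}.
#' @slot binNames,binBase names and common base rates of the binary features.
#' @slot binOffsets g x d_b matrix of per-unit-separation probability
#'   offsets, multiplied by \code{separation} and clamped to [0.01, 0.99].
#' @slot separation scalar multiplier on between-subgroup spacing.
#' @slot classRules list of g rules, each \code{list(feature, threshold,
#'   orientation)} with orientation ">" or "<" meaning "class 1 when beyond".
#' @slot labelNoise probability of flipping the rule class, in [0, 0.5).
#' @slot hazards per-subgroup exponential event rate per month.
#' @slot censorHorizon uniform censoring horizon C (months).
#' @export
setClass("SyntheticSpec",
  representation(n = "integer", g = "integer", weights = "numeric",
                 contNames = "character", contMeans = "numeric",
                 contSds = "matrix", contOffsets = "matrix",
                 binNames = "character", binBase = "numeric",
                 binOffsets = "matrix", separation = "numeric",
                 classRules = "list", labelNoise = "numeric",
                 hazards = "numeric", censorHorizon = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  g <- object@g
  if (length(object@weights) != g || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must have length g and sum to 1")
  if (any(object@contSds <= 0)) msg <- c(msg, "sds must be positive")
  if (any(object@hazards <= 0)) msg <- c(msg, "hazards must be positive")
  if (object@labelNoise < 0 || object@labelNoise >= 0.5)
    msg <- c(msg, "labelNoise must lie in [0, 0.5)")
  if (!all(dim(object@contOffsets) == c(g, length(object@contNames))))
    msg <- c(msg, "contOffsets must be g x d_c")
  if (!all(dim(object@contSds) == c(g, length(object@contNames))))
    msg <- c(msg, "contSds must be g x d_c")
  if (!all(dim(object@binOffsets) == c(g, length(object@binNames))))
    msg <- c(msg, "binOffsets must be g x d_b")
  if (length(object@classRules) != g)
    msg <- c(msg, "one class rule per subgroup required")
  if (length(object@hazards) != g)
    msg <- c(msg, "one hazard per subgroup required")
  if (object@separation < 0) msg <- c(msg, "separation must be nonnegative")
  if (length(msg)) msg else TRUE
})
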