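#' Kaplan-Meier product-limit estimator
#'
#' Estimates the probability of remaining event-free over time from
#' right-censored follow-up: at each distinct event time t_i the curve steps
#' down by the factor (1 - d_i / n_i), where d_i is the number of events at
#' t_i and n_i the number still at risk just before it; a censored patient
#' leaves the risk set at their time without triggering a step. With no
#' censoring the curve equals 1 minus the empirical CDF of the event times.
#'
#' @param times nonnegative follow-up times (months).
#' @param events 1 = event occurred, 0 = censored.
#' @return a \code{\linkS4class{KMCurve}}.
#' @export
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' kmSurvivalAt(km, 2)  # 2/3
kmEstimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(times < 0)) stop("times must be nonnegative", call. = FALSE)
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1", call. = FALSE)
  evTimes <- sort(unique(times[events == 1L]))
  nRisk <- integer(length(evTimes))
  nEvent <- integer(length(evTimes))
  surv <- numeric(length(evTimes))
  s <- 1
  for (i in seq_along(evTimes)) {
    t <- evTimes[i]
    nRisk[i] <- sum(times >= t)
    nEvent[i] <- sum(times == t & events == 1L)
    s <- s * (1 - nEvent[i] / nRisk[i])
    surv[i] <- s
  }
  new("KMCurve", time = evTimes, nRisk = nRisk, nEvent = nEvent, surv = surv)
}

#' Survival probability at a time point
#' @param curve a \code{\linkS4class{KMCurve}}.
#' @param t time (months).
#' @return S(t): 1 before the first event time.
#' @export
kmSurvivalAt <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve@time <= tt)
    if (i == 0L) 1 else curve@surv[i]
  }, 0)
}

#' Kaplan-Meier curve as a data frame
#' @param curve a \code{\linkS4class{KMCurve}}.
#' @return data.frame with columns time, n_risk, n_event, survival.
#' @export
kmAsDataFrame <- function(curve) {
  data.frame(time = curve@time, n_risk = curve@nRisk,
             n_event = curve@nEvent, survival = curve@surv)
}

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d event times", length(object@time)))
  if (length(object@time))
    cat(sprintf(", S(last = %.4g) = %.4f", max(object@time),
                object@surv[length(object@surv)]))
  cat("\n")
})

#' Kaplan-Meier curves per consensus cluster
#'
#' Routes every patient (training or held-out) to its linkage-nearest
#' consensus cluster and estimates one survival curve per cluster from the
#' table's time/event columns.
#'
#' @param model a fitted \code{\linkS4class{NccModel}}.
#' @param table a \code{\linkS4class{CohortTable}} with time and event columns.
#' @return named list of \code{\linkS4class{KMCurve}}s ("cluster1", ...).
#' @export
kmByCluster <- function(model, table) {
  if (!length(table@time) || !length(table@event))
    stop("time and event columns are required", call. = FALSE)
  tab <- imputeCohort(table, model@config$imputeStats)
  Xs <- applyScaler(model@scaler, tab@X)
  routed <- vapply(seq_len(nrow(Xs)), function(i)
    routeCluster(Xs[i, ], model), 0L)
  labs <- sort(unique(routed))
  out <- lapply(labs, function(lab) {
    sel <- routed == lab
    kmEstimate(table@time[sel], table@event[sel])
  })
  names(out) <- paste0("cluster", labs)
  out
}
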