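#' Construct a cohort schema
#'
#' @param featureNames character vector of feature column names.
#' @param featureKinds "continuous" or "binary", one per feature (a single
#'   value is recycled).
#' @param classColumn,timeColumn,eventColumn optional column names.
#' @param positiveClass class label treated as the positive (event-before-
#'   threshold) class; default "1".
#' @param recodeMaps named list of per-feature named numeric vectors mapping
#'   raw binary codes to 0/1, e.g. \code{list(gender = c("1" = 0, "2" = 1))}.
#' @return a \code{\linkS4class{CohortSchema}}.
#' @export
#' @examples
#' cohortSchema(c("Hb", "ACA"), c("continuous", "binary"), classColumn = "cls")
cohortSchema <- function(featureNames, featureKinds,
                         classColumn = NULL, timeColumn = NULL,
                         eventColumn = NULL, positiveClass = "1",
                         recodeMaps = list()) {
  if (length(featureKinds) == 1L)
    featureKinds <- rep(featureKinds, length(featureNames))
  new("CohortSchema",
      featureNames = as.character(featureNames),
      featureKinds = as.character(featureKinds),
      classColumn = as.character(classColumn %||% character(0)),
      timeColumn = as.character(timeColumn %||% character(0)),
      eventColumn = as.character(eventColumn %||% character(0)),
      positiveClass = as.character(positiveClass),
      recodeMaps = recodeMaps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort schema from a YAML config file
#' @param path path to a YAML file with fields \code{features} (list of
#'   \code{name}/\code{kind}/optional \code{recode}), and optional
#'   \code{class_column}, \code{time_column}, \code{event_column},
#'   \code{positive_class}.
#' @return a \code{\linkS4class{CohortSchema}}.
#' @export
readSchema <- function(path) {
  cfg <- yaml::read_yaml(path)
  feats <- cfg$features
  recodes <- list()
  for (f in feats) {
    if (!is.null(f$recode)) {
      v <- unlist(f$recode)
      recodes[[f$name]] <- stats::setNames(as.numeric(v), names(v))
    }
  }
  cohortSchema(
    featureNames = vapply(feats, `[[`, "", "name"),
    featureKinds = vapply(feats, `[[`, "", "kind"),
    classColumn = cfg$class_column, timeColumn = cfg$time_column,
    eventColumn = cfg$event_column,
    positiveClass = cfg$positive_class %||% "1",
    recodeMaps = recodes)
}

#' Write a cohort schema to YAML
#' @param schema a \code{\linkS4class{CohortSchema}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSchema <- function(schema, path) {
  feats <- lapply(seq_along(schema@featureNames), function(i) {
    f <- list(name = schema@featureNames[i], kind = schema@featureKinds[i])
    rm <- schema@recodeMaps[[schema@featureNames[i]]]
    if (!is.null(rm)) f$recode <- as.list(rm)
    f
  })
  cfg <- list(features = feats)
  if (length(schema@classColumn)) cfg$class_column <- schema@classColumn
  if (length(schema@timeColumn)) cfg$time_column <- schema@timeColumn
  if (length(schema@eventColumn)) cfg$event_column <- schema@eventColumn
  cfg$positive_class <- schema@positiveClass
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Construct a cohort table from in-memory data
#'
#' @param X numeric matrix (patients x features), colnames matching the schema.
#' @param schema a \code{\linkS4class{CohortSchema}}.
#' @param y optional character class labels.
#' @param time,event optional survival columns (months; 1 = event, 0 = censored).
#' @param rowIds optional stable row identifiers.
#' @return a \code{\linkS4class{CohortTable}}.
#' @export
cohortTable <- function(X, schema, y = NULL, time = NULL, event = NULL,
                        rowIds = NULL) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% schema@featureNames
  new("CohortTable", X = X,
      y = as.character(y %||% character(0)),
      time = as.numeric(time %||% numeric(0)),
      event = as.integer(event %||% integer(0)),
      rowIds = as.character(rowIds %||% as.character(seq_len(nrow(X)))),
      schema = schema)
}

#' Read a delimited cohort file under a schema
#'
#' Reads an RFC-4180 CSV with a header row, checks every schema column is
#' present, coerces continuous features to numeric (a non-numeric entry is a
#' hard error naming its row and column), applies declared recode maps to
#' binary features, and carries class/time/event columns through. Rows with a
#' missing class value are retained with an absent (NA) label.
#'
#' @param path path to the CSV file.
#' @param schema a \code{\linkS4class{CohortSchema}}.
#' @return a \code{\linkS4class{CohortTable}} (may still contain missing
#'   feature values; see \code{\link{imputeCohort}}).
#' @export
readCohort <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  needed <- c(schema@featureNames, schema@classColumn, schema@timeColumn,
              schema@eventColumn)
  missingCols <- setdiff(needed, names(df))
  if (length(missingCols))
    stop("cohort file is missing schema column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  d <- length(schema@featureNames)
  X <- matrix(NA_real_, nrow(df), d,
              dimnames = list(NULL, schema@featureNames))
  for (j in seq_len(d)) {
    nm <- schema@featureNames[j]
    raw <- df[[nm]]
    rmap <- schema@recodeMaps[[nm]]
    if (!is.null(rmap)) {
      bad <- !is.na(raw) & !(raw %in% names(rmap))
      if (any(bad))
        stop(sprintf("unmapped code '%s' in recoded column '%s' (row %d)",
                     raw[which(bad)[1]], nm, which(bad)[1]), call. = FALSE)
      X[, j] <- unname(rmap[raw])
    } else {
      val <- suppressWarnings(as.numeric(raw))
      bad <- !is.na(raw) & is.na(val)
      if (any(bad))
        stop(sprintf("non-numeric value '%s' in column '%s' (row %d)",
                     raw[which(bad)[1]], nm, which(bad)[1]), call. = FALSE)
      X[, j] <- val
    }
    if (schema@featureKinds[j] == "binary" &&
        !all(X[, j] %in% c(0, 1, NA)))
      stop(sprintf("binary column '%s' contains values other than 0/1; declare a recode map",
                   nm), call. = FALSE)
  }
  grab <- function(col, fn) if (length(col)) fn(df[[col]]) else fn(character(0))
  cohortTable(X, schema,
              y = grab(schema@classColumn, as.character),
              time = grab(schema@timeColumn,
                          function(v) suppressWarnings(as.numeric(v))),
              event = grab(schema@eventColumn,
                           function(v) as.integer(suppressWarnings(as.numeric(v)))))
}

#' Write a cohort table to CSV
#'
#' Numeric values are written with 17 significant digits so a write/read
#' round-trip reproduces the table exactly.
#'
#' @param table a \code{\linkS4class{CohortTable}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCohortCsv <- function(table, path) {
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  out <- as.data.frame(apply(table@X, 2, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (nrow(table@X) == 1L) out <- as.data.frame(t(out), check.names = FALSE)
  sc <- table@schema
  if (length(sc@classColumn) && length(table@y))
    out[[sc@classColumn]] <- ifelse(is.na(table@y), "", table@y)
  if (length(sc@timeColumn) && length(table@time))
    out[[sc@timeColumn]] <- fmt(table@time)
  if (length(sc@eventColumn) && length(table@event))
    out[[sc@eventColumn]] <- ifelse(is.na(table@event), "", as.character(table@event))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Impute missing feature values
#'
#' Continuous gaps are filled with the column median of observed values,
#' binary gaps with the column mode (ties toward 0). When \code{stats} from
#' \code{\link{fitImputeStats}} on a training set is supplied, those training
#' statistics are used instead (no test-set leakage inside evaluation splits).
#'
#' @param table a \code{\linkS4class{CohortTable}}.
#' @param stats optional output of \code{\link{fitImputeStats}}.
#' @return a new imputed \code{\linkS4class{CohortTable}}; the input is left
#'   untouched.
#' @export
imputeCohort <- function(table, stats = NULL) {
  if (is.null(stats)) stats <- fitImputeStats(table)
  X <- table@X
  for (j in seq_len(ncol(X))) {
    gap <- is.na(X[, j])
    if (any(gap)) X[gap, j] <- stats[j]
  }
  out <- table
  out@X <- X
  out
}

#' Fit per-feature imputation statistics (median / mode)
#' @param table a \code{\linkS4class{CohortTable}} of training rows.
#' @return named numeric vector of fill values, one per feature.
#' @export
fitImputeStats <- function(table) {
  sc <- table@schema
  vapply(seq_along(sc@featureNames), function(j) {
    v <- table@X[, j]
    obs <- v[!is.na(v)]
    if (!length(obs))
      stop(sprintf("feature '%s' is entirely missing", sc@featureNames[j]),
           call. = FALSE)
    if (sc@featureKinds[j] == "binary") {
      n1 <- sum(obs == 1)
      if (n1 > length(obs) - n1) 1 else 0  # ties -> 0
    } else stats::median(obs)
  }, 0, USE.NAMES = FALSE) -> out
  stats::setNames(out, sc@featureNames)
}

#' Fit a feature scaler on training rows
#'
#' Continuous features are centered on the training mean and divided by the
#' training sample standard deviation (divisor n-1); a constant feature gets
#' spread 1 so it maps to 0. Binary features pass through unchanged.
#'
#' @param table a \code{\linkS4class{CohortTable}} of training rows (imputed).
#' @return a \code{\linkS4class{Scaler}}.
#' @export
fitScaler <- function(table) {
  sc <- table@schema
  d <- ncol(table@X)
  center <- numeric(d); spread <- numeric(d)
  for (j in seq_len(d)) {
    if (sc@featureKinds[j] == "binary") {
      center[j] <- 0; spread[j] <- 1
    } else {
      v <- table@X[, j]
      center[j] <- mean(v)
      s <- stats::sd(v)
      spread[j] <- if (is.na(s) || s == 0) 1 else s
    }
  }
  new("Scaler", center = center, spread = spread, kind = sc@featureKinds)
}

#' Apply a fitted scaler to a feature matrix
#' @param scaler a \code{\linkS4class{Scaler}} fitted on training rows.
#' @param X numeric matrix with the training dimensionality.
#' @return the standardized matrix.
#' @export
applyScaler <- function(scaler, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler@center))
    stop("matrix has wrong dimensionality for this scaler", call. = FALSE)
  sweep(sweep(X, 2, scaler@center, "-"), 2, scaler@spread, "/")
}

#' Derive binary classes from time-to-event columns
#'
#' Implements the cohort-selection rule used for the 5-year endpoints: a
#' patient whose event occurred at or before the threshold is class "1"; a
#' patient followed beyond the threshold without the event by then (whether
#' the event or censoring came later) is class "2"; a patient censored before
#' the threshold without the event belongs to neither group and is excluded.
#'
#' @param table a \code{\linkS4class{CohortTable}} with time and event columns.
#' @param thresholdMonths positive threshold; default 60 (5 years).
#' @return list with \code{labels} (character, NA where excluded) and
#'   \code{included} (logical mask).
#' @export
#' @examples
#' sc <- cohortSchema("a", "continuous", timeColumn = "t", eventColumn = "e")
#' tb <- cohortTable(matrix(1:3, ncol = 1), sc,
#'                   time = c(30, 70, 40), event = c(1L, 0L, 0L))
#' labelTimeToEvent(tb)$labels  # "1", "2", NA
labelTimeToEvent <- function(table, thresholdMonths = 60) {
  if (!length(table@time) || !length(table@event))
    stop("time and event columns are required", call. = FALSE)
  if (any(table@time < 0, na.rm = TRUE))
    stop("negative time-to-event encountered", call. = FALSE)
  stopifnot(thresholdMonths > 0)
  lab <- rep(NA_character_, nrow(table@X))
  occurred <- table@event == 1L
  lab[occurred & table@time <= thresholdMonths] <- "1"
  lab[is.na(lab) & table@time >= thresholdMonths] <- "2"
  list(labels = lab, included = !is.na(lab))
}

#' Subset a cohort table by row
#' @param table a \code{\linkS4class{CohortTable}}.
#' @param i row indices or logical mask.
#' @return the subset \code{\linkS4class{CohortTable}}.
#' @export
subsetCohort <- function(table, i) {
  pick <- function(v) if (length(v)) v[i] else v
  new("CohortTable", X = table@X[i, , drop = FALSE],
      y = pick(table@y), time = pick(table@time), event = pick(table@event),
      rowIds = table@rowIds[i], schema = table@schema)
}

#' Number of patients in a cohort
#' @param table a \code{\linkS4class{CohortTable}}.
#' @return integer row count.
#' @export
nRows <- function(table) nrow(table@X)

#' Feature matrix accessor
#' @param table a \code{\linkS4class{CohortTable}}.
#' @return the numeric feature matrix.
#' @export
featureMatrix <- function(table) table@X

#' Class label accessor
#' @param table a \code{\linkS4class{CohortTable}}.
#' @return character labels (length 0 when absent).
#' @export
classLabels <- function(table) table@y

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d patients x %d features (%d continuous, %d binary)\n",
              nrow(object@X), ncol(object@X),
              sum(object@schema@featureKinds == "continuous"),
              sum(object@schema@featureKinds == "binary")))
  if (length(object@y))
    cat("  class labels:", paste(names(table(object@y)), table(object@y),
                                 sep = "=", collapse = ", "),
        if (anyNA(object@y)) sprintf("(%d unlabeled)", sum(is.na(object@y))) else "",
        "\n")
  if (length(object@time))
    cat(sprintf("  survival: %d events / %d censored\n",
                sum(object@event == 1L, na.rm = TRUE),
                sum(object@event == 0L, na.rm = TRUE)))
})

setMethod("show", "CohortSchema", function(object) {
  cat(sprintf("CohortSchema: %d features (%d continuous, %d binary)\n",
              length(object@featureNames),
              sum(object@featureKinds == "continuous"),
              sum(object@featureKinds == "binary")))
  if (length(object@classColumn)) cat("  class column:", object@classColumn, "\n")
  if (length(object@timeColumn))
    cat("  survival columns:", object@timeColumn, "/", object@eventColumn, "\n")
})
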