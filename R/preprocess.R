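#' Continuous parcel time series
#'
#' @param values numeric matrix, parcels in rows, time points in columns.
#' @param parcel_labels optional parcel names.
#' @param cadence sampling cadence in seconds (metadata only).
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(values, parcel_labels = NULL, cadence = 2) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (nrow(values) < 1 || ncol(values) < 2)
    stop("need at least 1 parcel and 2 time points")
  if (is.null(parcel_labels)) parcel_labels <- default_parcel_labels(nrow(values))
  if (length(parcel_labels) != nrow(values))
    stop("parcel_labels length mismatch")
  structure(list(values = unname(values), parcel_labels = parcel_labels,
                 cadence = cadence),
            class = "parcel_ts")
}

#' Binarized spin-state series
#'
#' @param states matrix in `{-1, +1}`, parcels in rows, time in columns.
#' @param parcel_labels optional parcel names.
#' @param pairing optional homotopic pairing (involution on parcel indices).
#' @param provenance free-form list recording where the series came from.
#' @return An object of class `binary_series`.
#' @export
binary_series <- function(states, parcel_labels = NULL, pairing = NULL,
                          provenance = list()) {
  states <- as.matrix(states)
  if (!all(states %in% c(-1, 1))) stop("states must be exactly -1 or +1")
  if (ncol(states) < 2) stop("need at least 2 time points")
  n <- nrow(states)
  if (is.null(parcel_labels)) parcel_labels <- default_parcel_labels(n)
  if (length(parcel_labels) != n) stop("parcel_labels length mismatch")
  if (is.null(pairing) && n %% 2 == 0) pairing <- mirror_pairing(n)
  if (!is.null(pairing)) pairing <- validate_pairing(pairing, n)
  structure(list(states = unname(states), parcel_labels = parcel_labels,
                 pairing = pairing, provenance = provenance),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("Binary series: %d parcels x %d time points\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Binarize a parcel time series at the per-parcel median
#'
#' Each parcel is thresholded at the median of its own time course: values
#' strictly greater than the median map to +1, values less than or equal to
#' it map to -1. For tie-free data this splits each row as evenly as the
#' length allows, so the entropy of each binarized series is (near) maximal.
#' Ties at the median map to -1 by the strictly-greater rule.
#'
#' @param ts a [parcel_ts()] (or a plain numeric matrix).
#' @return A [binary_series()] with the same parcel labels. A warning is
#'   emitted for constant rows, which binarize to all -1 and carry no signal.
#' @export
binarize_median <- function(ts) {
  if (is.matrix(ts)) ts <- parcel_ts(ts)
  stopifnot(inherits(ts, "parcel_ts"))
  v <- ts$values
  med <- apply(v, 1, median)
  states <- ifelse(v > med, 1, -1)
  constant <- apply(v, 1, function(r) all(r == r[1]))
  if (any(constant))
    warning(sprintf("constant parcel row(s) %s binarize to all -1",
                    paste(which(constant), collapse = ", ")))
  binary_series(states, parcel_labels = ts$parcel_labels,
                provenance = list(source = "binarize_median"))
}

#' Concatenate binary sessions along the time axis
#'
#' @param series list of [binary_series()] with identical parcel labels and
#'   pairing, in the order they should be joined.
#' @return One [binary_series()]; provenance lists the inputs' provenance.
#' @export
concatenate_sessions <- function(series) {
  if (inherits(series, "binary_series")) series <- list(series)
  stopifnot(length(series) >= 1)
  first <- series[[1]]
  for (s in series) {
    stopifnot(inherits(s, "binary_series"))
    if (nrow(s$states) != nrow(first$states) ||
        !identical(s$parcel_labels, first$parcel_labels))
      stop("parcel labels differ between sessions")
    if (!identical(s$pairing, first$pairing))
      stop("homotopic pairing differs between sessions")
  }
  binary_series(do.call(cbind, lapply(series, `[[`, "states")),
                parcel_labels = first$parcel_labels,
                pairing = first$pairing,
                provenance = list(source = "concatenate_sessions",
                                  parts = lapply(series, `[[`, "provenance")))
}

#' Assemble concatenated binary data over a cohort scope
#'
#' Concatenates sessions in deterministic manifest order: subjects ascending,
#' conditions in manifest order within subject, sessions ascending within
#' condition. `scope = "global"` takes everything (the input to the global
#' archetype fit), `"condition"` one condition across subjects, and
#' `"subject_condition"` one subject in one condition.
#'
#' @param cohort a cohort object (see [simulate_cohort()] / [read_cohort()]).
#' @param scope `"global"`, `"condition"`, or `"subject_condition"`.
#' @param condition condition label (required unless scope is global).
#' @param subject subject identifier (required for subject_condition scope).
#' @return A [binary_series()].
#' @export
assemble_condition_data <- function(cohort,
                                    scope = c("global", "condition",
                                              "subject_condition"),
                                    condition = NULL, subject = NULL) {
  scope <- match.arg(scope)
  man <- cohort$manifest
  subjects <- man$subjects
  conditions <- man$conditions
  if (scope != "global") {
    if (is.null(condition) || !condition %in% conditions)
      stop("condition must be one of the manifest conditions")
    conditions <- condition
  }
  if (scope == "subject_condition") {
    if (is.null(subject) || !subject %in% subjects)
      stop("subject must be one of the manifest subjects")
    subjects <- subject
  }
  keys <- character(0)
  for (s in subjects)
    for (co in conditions)
      for (se in seq_len(man$sessions_per_condition))
        keys <- c(keys, series_key(s, co, se))
  missing <- setdiff(keys, names(cohort$series))
  if (length(missing))
    stop("missing series for: ", paste(missing, collapse = ", "))
  concatenate_sessions(cohort$series[keys])
}

series_key <- function(subject, condition, session) {
  paste(subject, condition, session, sep = "|")
}
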