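#' Cohort manifest
#'
#' Indexes the on-disk series of a cohort: which file holds which
#' (subject, condition, session) matrix, the shared parcel labels, and the
#' homotopic pairing. Manifests are stored as YAML; pairing indices are
#' 1-based in R and on disk.
#'
#' @param subjects character vector of subject identifiers.
#' @param conditions character vector of condition labels.
#' @param sessions_per_condition sessions per subject and condition.
#' @param parcel_labels ordered parcel names.
#' @param pairing homotopic pairing (fixed-point-free involution).
#' @param files optional named character vector of relative paths keyed
#'   `subject|condition|session`.
#' @return An object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(subjects, conditions, sessions_per_condition,
                            parcel_labels, pairing = NULL, files = NULL) {
  n <- length(parcel_labels)
  if (is.null(pairing) && n %% 2 == 0) pairing <- mirror_pairing(n)
  if (!is.null(pairing)) pairing <- validate_pairing(pairing, n)
  keys <- character(0)
  for (s in subjects)
    for (co in conditions)
      for (se in seq_len(sessions_per_condition))
        keys <- c(keys, series_key(s, co, se))
  if (!is.null(files)) {
    if (!setequal(names(files), keys))
      stop("files must cover every (subject, condition, session) exactly once")
    files <- files[keys]
  }
  structure(list(subjects = as.character(subjects),
                 conditions = as.character(conditions),
                 sessions_per_condition = as.integer(sessions_per_condition),
                 parcel_labels = as.character(parcel_labels),
                 pairing = pairing, files = files),
            class = "cohort_manifest")
}

#' Read a parcel time-series matrix from delimited text
#'
#' Rows are parcels, columns are time points. The delimiter (comma or
#' whitespace) is auto-detected. Non-numeric cells raise a parse error
#' naming the offending row and column.
#'
#' @param path file path.
#' @param expected_parcels optional parcel count to enforce.
#' @return A [parcel_ts()] (or [binary_series()] if every value is -1/+1 --
#'   binarized matrices round-trip through the same format).
#' @param as_binary force interpretation as a binary series.
#' @export
read_timeseries <- function(path, expected_parcels = NULL, as_binary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  toks <- strsplit(trimws(lines), if (sep_comma) "\\s*,\\s*" else "\\s+")
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1)
    stop(sprintf("ragged rows in %s: %s columns", path,
                 paste(ncols, collapse = " vs ")))
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1]
      stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                   toks[[i]][j], i, j, path))
    }
  }
  m <- do.call(rbind, vals)
  if (!is.null(expected_parcels) && nrow(m) != expected_parcels)
    stop(sprintf("%s has %d parcels, expected %d", path, nrow(m),
                 expected_parcels))
  if (as_binary || all(m %in% c(-1, 1))) binary_series(m) else parcel_ts(m)
}

#' Write a time-series or binary matrix as delimited text
#'
#' @param x a [parcel_ts()], [binary_series()], or plain matrix.
#' @param path output path.
#' @param digits significant digits retained (default keeps full precision).
#' @export
write_timeseries <- function(x, path, digits = 17) {
  m <- if (inherits(x, "parcel_ts")) x$values
       else if (inherits(x, "binary_series")) x$states
       else as.matrix(x)
  lines <- apply(m, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize an Ising model to JSON
#'
#' Lossless round-trip of `h`, `J`, `beta` (absence preserved), parcel
#' labels, and pairing. [read_model()] re-validates the invariants, so a
#' hand-edited file with an asymmetric `J` is rejected.
#'
#' @param model an [ising_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  validate_ising_model(model)
  obj <- list(h = model$h, J = model$J,
              parcel_labels = model$parcel_labels)
  if (!is.null(model$beta)) obj$beta <- model$beta
  if (!is.null(model$pairing)) obj$pairing <- model$pairing
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @return [read_model()] returns the deserialized [ising_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ising_model(obj$h, obj$J, beta = obj$beta,
              parcel_labels = obj$parcel_labels,
              pairing = obj$pairing)
}

#' Write / read a cohort manifest as YAML
#'
#' @param manifest a [cohort_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  obj <- unclass(manifest)
  obj$files <- as.list(obj$files)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  files <- if (length(obj$files)) unlist(obj$files) else NULL
  cohort_manifest(obj$subjects, obj$conditions, obj$sessions_per_condition,
                  obj$parcel_labels, pairing = obj$pairing, files = files)
}

#' Write a cohort (manifest + series files) to a directory
#'
#' Series are written as one delimited text matrix per
#' (subject, condition, session); ground-truth temperatures and the
#' generating archetype, when present, are stored alongside.
#'
#' @param cohort an `ising_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  files <- character(0)
  for (key in names(cohort$series)) {
    fn <- paste0(gsub("[|]", "_", key), ".txt")
    write_timeseries(cohort$series[[key]], file.path(dir, fn))
    files[key] <- fn
  }
  man$files <- files
  write_manifest(man, file.path(dir, "manifest.yaml"))
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    write_model(gt$archetype, file.path(dir, "archetype_truth.json"))
    tt <- as.data.frame(gt$temperatures)
    tt <- cbind(subject = rownames(gt$temperatures), tt)
    utils::write.table(tt, file.path(dir, "temperatures_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file.path(dir, "manifest.yaml"))
}

#' @rdname write_cohort
#' @param manifest_path path to a manifest written by [write_cohort()].
#' @return [read_cohort()] returns the reassembled `ising_cohort` (without
#'   ground truth unless the truth files are present).
#' @export
read_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  if (is.null(man$files)) stop("manifest carries no file table")
  dir <- dirname(manifest_path)
  series <- list()
  for (key in names(man$files)) {
    x <- read_timeseries(file.path(dir, man$files[key]),
                         expected_parcels = length(man$parcel_labels))
    if (inherits(x, "parcel_ts"))
      stop("cohort series must be binarized (-1/+1): ", man$files[key])
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    series[[key]] <- binary_series(x$states, parcel_labels = man$parcel_labels,
                                   pairing = man$pairing,
                                   provenance = list(subject = parts[1],
                                                     condition = parts[2],
                                                     session = parts[3]))
  }
  gt <- NULL
  truth_model <- file.path(dir, "archetype_truth.json")
  truth_temp <- file.path(dir, "temperatures_truth.tsv")
  if (file.exists(truth_model) && file.exists(truth_temp)) {
    tt <- utils::read.table(truth_temp, header = TRUE, sep = "\t",
                            check.names = FALSE)
    temps <- as.matrix(tt[, -1, drop = FALSE])
    rownames(temps) <- tt$subject
    gt <- list(archetype = read_model(truth_model), temperatures = temps)
  }
  structure(list(manifest = man, series = series, ground_truth = gt),
            class = "ising_cohort")
}
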