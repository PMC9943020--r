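#' Flatten a binary series into a 0/1 string
#'
#' Maps +1 to '1' and -1 to '0'. With the default ordering the parcel index
#' runs fastest within each time frame and frames follow in time order, i.e.
#' the matrix is read column by column ("space then time"). The alternative
#' ordering reads each parcel's full time course in turn, exposed for
#' sensitivity checks.
#'
#' @param data a [binary_series()] or a -1/+1 matrix (parcels x time).
#' @param order `"space_then_time"` (default) or `"time_then_space"`.
#' @return A single character string over \{0, 1\}.
#' @export
flatten_binary <- function(data, order = c("space_then_time",
                                           "time_then_space")) {
  order <- match.arg(order)
  m <- if (inherits(data, "binary_series")) data$states else as.matrix(data)
  if (!all(m %in% c(-1, 1))) stop("data must be -1/+1")
  v <- if (order == "space_then_time") as.vector(m) else as.vector(t(m))
  spins_to_string(v)
}

spins_to_string <- function(v) {
  intToUtf8(ifelse(v > 0, 49L, 48L))  # '1' / '0'
}

#' Reconstruct a -1/+1 matrix from a flattened string
#'
#' @param s binary string from [flatten_binary()].
#' @param n_parcels,t_max dimensions of the original matrix.
#' @param order the ordering used to flatten.
#' @return A -1/+1 matrix of the given dimensions.
#' @export
unflatten_binary <- function(s, n_parcels, t_max,
                             order = c("space_then_time", "time_then_space")) {
  order <- match.arg(order)
  v <- ifelse(utf8ToInt(s) == 49L, 1, -1)
  if (length(v) != n_parcels * t_max) stop("string length does not match dims")
  if (order == "space_then_time") matrix(v, n_parcels, t_max)
  else t(matrix(v, t_max, n_parcels))
}

#' LZW dictionary
#'
#' An ordered word-to-code table over the binary alphabet. Must contain both
#' single-symbol words and be prefix-closed (every word's one-shorter prefix
#' present), which is automatic for dictionaries produced by an LZW pass.
#'
#' @param words character vector of words in insertion (code) order.
#' @return An object of class `lzw_dictionary`.
#' @export
lzw_dictionary <- function(words) {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("dictionary words must be unique")
  if (!all(c("0", "1") %in% words))
    stop("dictionary must contain both single-symbol words")
  if (length(bad <- setdiff(unique(unlist(strsplit(words, ""))), c("0", "1"))))
    stop("non-binary symbols in dictionary: ", paste(bad, collapse = ", "))
  longer <- words[nchar(words) > 1]
  prefixes <- substr(longer, 1, nchar(longer) - 1)
  if (!all(prefixes %in% words)) stop("dictionary is not prefix-closed")
  structure(list(words = words), class = "lzw_dictionary")
}

#' @export
print.lzw_dictionary <- function(x, ...) {
  cat(sprintf("LZW dictionary: %d words, longest %d symbols\n",
              length(x$words), max(nchar(x$words))))
  invisible(x)
}

#' LZW compression and description-length complexity
#'
#' Standard LZW parse (longest dictionary match, emit its code, insert the
#' match extended by the next symbol). The description length is taken as
#' \eqn{\ell = c(n)\log_2 c(n)} -- the number of emitted codes times the bits
#' needed to name a word -- and the complexity rate is \eqn{\rho_0 = \ell/n}
#' in bits per character, which for long strings converges from above to the
#' source entropy rate. The exact sum of emitted code widths is available as
#' `code_length = "emitted_widths"`.
#'
#' @param s binary string over \{0, 1\}.
#' @param seed_dictionary optional [lzw_dictionary()] used as the initial
#'   dictionary (it is still extended during the pass).
#' @param code_length description-length formula, `"cn_log2cn"` (default) or
#'   `"emitted_widths"`.
#' @return An object of class `lzw_result` with `n`, `c_n`, `ell`, `rho0`,
#'   `codes`, `dictionary` (the final [lzw_dictionary()]), `dictionary_size`,
#'   and `seeded`.
#' @export
lzw_compress <- function(s, seed_dictionary = NULL,
                         code_length = c("cn_log2cn", "emitted_widths")) {
  code_length <- match.arg(code_length)
  seed_words <- character(0)
  if (!is.null(seed_dictionary)) {
    stopifnot(inherits(seed_dictionary, "lzw_dictionary"))
    seed_words <- seed_dictionary$words
  }
  res <- lzw_compress_cpp(s, seed_words)
  c_n <- res$n_codes
  n <- nchar(s)
  ell <- if (code_length == "cn_log2cn") {
    if (c_n > 1) c_n * log2(c_n) else 1
  } else {
    init <- max(length(seed_words), 2)
    sizes <- init + seq_len(c_n) - 1
    sum(ceiling(log2(pmax(sizes, 2))))
  }
  structure(list(n = n, c_n = c_n, ell = ell, rho0 = ell / n,
                 codes = res$codes,
                 dictionary = lzw_dictionary(res$dict_words),
                 dictionary_size = length(res$dict_words),
                 seeded = length(seed_words) > 0),
            class = "lzw_result")
}

#' @export
print.lzw_result <- function(x, ...) {
  cat(sprintf("LZW: n = %d, c(n) = %d, ell = %.1f, rho0 = %.4f bits/char%s\n",
              x$n, x$c_n, x$ell, x$rho0, if (x$seeded) " (seeded)" else ""))
  invisible(x)
}

#' Decompress an LZW code sequence
#'
#' @param codes integer codes from [lzw_compress()].
#' @param seed_dictionary the same seed dictionary used for compression, if any.
#' @return The original binary string.
#' @export
lzw_decompress <- function(codes, seed_dictionary = NULL) {
  seed_words <- character(0)
  if (!is.null(seed_dictionary)) {
    stopifnot(inherits(seed_dictionary, "lzw_dictionary"))
    seed_words <- seed_dictionary$words
  }
  lzw_decompress_cpp(as.integer(codes), seed_words)
}

#' Build the archetype dictionary from a cohort
#'
#' Flattens and concatenates every session of the cohort -- the first listed
#' condition first, then the second; subjects ascending and sessions in order
#' within each condition -- compresses the result once, and returns the final
#' dictionary. Seeding per-subject compressions with this dictionary scores
#' each subject's data against the vocabulary of the whole cohort.
#'
#' @param cohort an `ising_cohort`.
#' @param condition_order optional reordering of the manifest conditions.
#' @param order flattening order passed to [flatten_binary()].
#' @return An [lzw_dictionary()].
#' @export
build_archetype_dictionary <- function(cohort, condition_order = NULL,
                                       order = "space_then_time") {
  man <- cohort$manifest
  conditions <- condition_order %||% man$conditions
  if (!setequal(conditions, man$conditions))
    stop("condition_order must be a permutation of the manifest conditions")
  if (length(cohort$series) == 0) stop("cohort has no series")
  parts <- character(0)
  for (co in conditions)
    for (s in man$subjects)
      for (se in seq_len(man$sessions_per_condition))
        parts <- c(parts, flatten_binary(cohort$series[[series_key(s, co, se)]],
                                         order = order))
  lzw_compress(paste(parts, collapse = ""))$dictionary
}

#' CTM lookup table for the Block Decomposition Method
#'
#' Maps binary blocks (given as row-major bit strings) of a fixed shape to
#' algorithmic-probability-derived complexity values. Published CTM tables
#' can be loaded with [read_ctm_table()]; blocks absent from the table are
#' scored by the declared fallback.
#'
#' @param values named numeric vector: names are bit strings of length
#'   `prod(block_shape)`, values the CTM complexities in bits.
#' @param block_shape integer vector `c(rows, cols)`.
#' @param provenance free-form provenance tag.
#' @return An object of class `ctm_table`.
#' @export
ctm_table <- function(values, block_shape, provenance = "user") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  len <- prod(block_shape)
  if (!all(nchar(names(values)) == len))
    stop("block strings must have length prod(block_shape)")
  structure(list(values = values, block_shape = as.integer(block_shape),
                 provenance = provenance),
            class = "ctm_table")
}

#' Read / write a CTM table as delimited text
#'
#' One `block-bitstring value` pair per line, whitespace-separated, with a
#' `# block_shape: r c` header line.
#'
#' @param table a [ctm_table()].
#' @param path file path.
#' @export
write_ctm_table <- function(table, path) {
  stopifnot(inherits(table, "ctm_table"))
  writeLines(c(sprintf("# block_shape: %d %d", table$block_shape[1],
                       table$block_shape[2]),
               sprintf("%s %.17g", names(table$values), table$values)),
             path)
  invisible(path)
}

#' @rdname write_ctm_table
#' @export
read_ctm_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*block_shape:", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing '# block_shape: r c' header in ", path)
  shape <- as.integer(strsplit(sub("^#\\s*block_shape:\\s*", "", hdr),
                               "\\s+")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(body), "\\s+")
  vals <- vapply(toks, function(t) as.numeric(t[2]), numeric(1))
  names(vals) <- vapply(toks, `[[`, character(1), 1)
  ctm_table(vals, shape, provenance = path)
}

#' Read / write an LZW dictionary as text (one word per line, code order)
#'
#' @param dictionary an [lzw_dictionary()].
#' @param path file path.
#' @export
write_lzw_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "lzw_dictionary"))
  writeLines(dictionary$words, path)
  invisible(path)
}

#' @rdname write_lzw_dictionary
#' @export
read_lzw_dictionary <- function(path) {
  lzw_dictionary(readLines(path))
}

#' Block Decomposition Method complexity
#'
#' Partitions a binary matrix into non-overlapping blocks (boundary
#' remainders discarded) and scores
#' \deqn{\mathrm{BDM} = \sum_{b\ \mathrm{distinct}} \mathrm{CTM}(b) + \log_2 m_b,}
#' the CTM complexity of each distinct block plus the log of its
#' multiplicity. Blocks missing from the CTM table (or all blocks, when no
#' table is given) are scored by the fallback; the default fallback is the
#' block's Shannon entropy in bits, `n_cells * H(p)` with `p` the fraction of
#' ones, and the share of distinct blocks scored this way is reported.
#'
#' @param data -1/+1 or 0/1 binary matrix, or a [binary_series()].
#' @param table optional [ctm_table()].
#' @param block_shape `c(rows, cols)` of the partition blocks.
#' @param fallback `"entropy"` or `"none"` (error on a missing block).
#' @return An object of class `bdm_result` with `bdm`, `block_shape`,
#'   `n_blocks`, `n_distinct`, and `fallback_fraction`.
#' @export
bdm <- function(data, table = NULL, block_shape = c(4, 4),
                fallback = c("entropy", "none")) {
  fallback <- match.arg(fallback)
  m <- if (inherits(data, "binary_series")) data$states else as.matrix(data)
  if (all(m %in% c(-1, 1))) m <- (m + 1) / 2
  if (!all(m %in% c(0, 1))) stop("data must be binary (-1/+1 or 0/1)")
  if (!is.null(table)) {
    stopifnot(inherits(table, "ctm_table"))
    if (!identical(as.integer(block_shape), table$block_shape))
      stop("block_shape does not match the CTM table")
  }
  br <- block_shape[1]; bc <- block_shape[2]
  nr <- nrow(m) %/% br; nc <- ncol(m) %/% bc
  if (nr < 1 || nc < 1)
    stop("data smaller than one block after boundary trimming")
  keys <- character(nr * nc)
  k <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      blk <- m[((i - 1) * br + 1):(i * br), ((j - 1) * bc + 1):(j * bc)]
      k <- k + 1
      keys[k] <- paste(as.integer(t(blk)), collapse = "")  # row-major
    }
  }
  counts <- base::table(keys)   # explicit: `table` is an argument here
  uniq <- names(counts)
  ctm_vals <- numeric(length(uniq))
  miss <- logical(length(uniq))
  for (u in seq_along(uniq)) {
    v <- if (!is.null(table)) table$values[uniq[u]] else NA_real_
    if (is.null(v) || is.na(v)) {
      if (fallback == "none")
        stop("block absent from CTM table and fallback disabled: ", uniq[u])
      miss[u] <- TRUE
      p <- mean(utf8ToInt(uniq[u]) == 49L)
      ctm_vals[u] <- length(utf8ToInt(uniq[u])) * binary_entropy(p)
    } else {
      ctm_vals[u] <- v
    }
  }
  structure(list(bdm = sum(ctm_vals + log2(as.numeric(counts))),
                 block_shape = as.integer(block_shape),
                 n_blocks = nr * nc, n_distinct = length(uniq),
                 fallback_fraction = mean(miss)),
            class = "bdm_result")
}

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

#' @export
print.bdm_result <- function(x, ...) {
  cat(sprintf("BDM: %.2f bits over %d blocks (%d distinct, %.0f%% fallback)\n",
              x$bdm, x$n_blocks, x$n_distinct, 100 * x$fallback_fraction))
  invisible(x)
}
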