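#' Read a genes x time-points expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose first row is a header (a corner
#' cell followed by the time-point labels) and whose subsequent rows hold a
#' gene identifier followed by one numeric (or missing) value per time point.
#' This is the layout of time-course microarray matrices as deposited in
#' repositories such as Newt-Omics.
#'
#' Missing values may be encoded as an empty field, `NA`, `NaN` or `null`
#' (case-insensitive) — the common microarray export dialects. Duplicated
#' gene identifiers (after normalization) are resolved by `duplicate_policy`:
#' `"first"` keeps the first occurrence, `"mean"` collapses duplicates to
#' their per-time-point mean; either way the number affected is reported
#' via [message()].
#'
#' @param path path to the TSV file.
#' @param case_insensitive logical; normalize gene identifiers by trimming
#'   whitespace and lower-casing (default `TRUE`, matching the downstream
#'   set-matching convention).
#' @param duplicate_policy `"first"` or `"mean"`.
#' @param na_tokens character vector of field values parsed as missing.
#' @return An [expression_matrix()] preserving file row and column order
#'   (minus resolved duplicates).
#' @export
read_expression_matrix <- function(path,
                                   case_insensitive = TRUE,
                                   duplicate_policy = c("first", "mean"),
                                   na_tokens = c("", "na", "nan", "null")) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path))
    stop(sprintf("expression matrix file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression matrix file must contain a header and at least one gene row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  m <- length(header) - 1L
  if (m < 2L)
    stop("expression matrix must have at least two time-point columns",
         call. = FALSE)
  time_labels <- trimws(header[-1L])
  if (anyDuplicated(time_labels))
    stop(sprintf("duplicate time-point label: '%s'",
                 time_labels[duplicated(time_labels)][1L]), call. = FALSE)
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != m + 1L)
  if (length(bad))
    stop(sprintf(
      "ragged row at line %d: expected %d fields, found %d",
      bad[1L] + 1L, m + 1L, widths[bad[1L]]
    ), call. = FALSE)

  ids <- normalize_ids(vapply(body, `[[`, character(1L), 1L), case_insensitive)
  vals <- vapply(body, function(f) {
    v <- trimws(f[-1L])
    v[tolower(v) %in% na_tokens] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(m))
  mat <- t(matrix(vals, nrow = m))

  dup <- duplicated(ids)
  if (any(dup)) {
    n_dup <- sum(dup)
    if (duplicate_policy == "first") {
      mat <- mat[!dup, , drop = FALSE]
      ids <- ids[!dup]
      message(sprintf("dropped %d duplicate gene id(s), keeping first occurrence",
                      n_dup))
    } else {
      keep <- unique(ids)
      mat <- rowsum(mat, group = factor(ids, levels = keep)) /
        as.vector(table(factor(ids, levels = keep)))
      ids <- keep
      message(sprintf("collapsed %d duplicate gene id(s) by per-column mean",
                      n_dup))
    }
  }
  expression_matrix(mat, ids, time_labels)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: header row with a `gene_id` corner
#' cell and the time labels, then one row per gene.
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Parses the Broad GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more member identifiers. Duplicate
#' members within a line are removed (with a [message()]); a duplicate set
#' name or a line with fewer than three fields is an error.
#'
#' @param path path to the GMT file.
#' @param case_insensitive logical; normalize member identifiers by trimming
#'   and lower-casing, matching [read_expression_matrix()].
#' @return A [gene_set_collection()] in file order.
#' @export
read_gmt <- function(path, case_insensitive = TRUE) {
  if (!file.exists(path))
    stop(sprintf("GMT file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("GMT file contains no gene sets", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  nms <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) {
    m <- normalize_ids(f[-(1:2)], case_insensitive)
    m[nzchar(m)]
  })
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1L)))
  if (n_dup > 0L) {
    members <- lapply(members, unique)
    message(sprintf("removed %d duplicate member id(s) within gene sets", n_dup))
  }
  names(members) <- nms
  gene_set_collection(members, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param sets a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$descriptions[[nm]], sets$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment results table to TSV
#'
#' Serializes the output of [run_analysis()] to a tab-separated table with
#' columns `set_name`, `set_size`, `overlap`, `d`, `p_raw`, `p_adj`,
#' `significant` (adjusted p below the configured alpha) and then one column
#' per time point holding the set's scaled mean profile. Rows are ordered by
#' raw p-value ascending with ties broken by set name; untestable sets
#' (overlap below the minimum) come last with empty statistics. Numeric
#' fields are printed with 6 significant digits.
#'
#' @param results a `bootgsa_result` from [run_analysis()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "bootgsa_result"))
  df <- results_table(results)
  num <- vapply(df, is.numeric, logical(1L))
  num["set_size"] <- num["overlap"] <- FALSE
  df[num] <- lapply(df[num], function(v) {
    out <- rep(NA_character_, length(v))
    out[!is.na(v)] <- formatC(signif(v[!is.na(v)], 6L), format = "g",
                              digits = 6L)
    out
  })
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop(sprintf("cannot write results to '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Assemble the flat results data.frame (statistics + profile columns) in the
# canonical output order: p_raw ascending, ties by name, untestable rows last.
results_table <- function(results) {
  df <- results$table
  prof <- results$profiles
  tl <- results$time_labels
  pm <- matrix(NA_real_, nrow = nrow(df), ncol = length(tl),
               dimnames = list(NULL, tl))
  if (!is.null(prof) && nrow(prof) > 0L) {
    hit <- match(rownames(prof), df$set_name)
    pm[hit, ] <- prof
  }
  out <- cbind(
    df[c("set_name", "set_size", "overlap", "d", "p_raw", "p_adj",
         "significant")],
    as.data.frame(pm, check.names = FALSE)
  )
  ord <- order(out$p_raw, out$set_name, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
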