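#' Construct an expression matrix object
#'
#' A light container for a genes x time-points expression matrix: row
#' identifiers (genes), ordered column labels (time points) and a numeric
#' matrix of values. Time labels are treated as opaque ordered strings; the
#' downstream distance statistic is insensitive to the (unequal) spacing of
#' the sampling grid, so no attempt is made to parse units.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#'   May contain `NA` before filtering.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param time_labels character vector of unique time-point labels, one per
#'   column. At least two time points are required.
#' @return An object of class `expression_matrix` with fields `gene_ids`,
#'   `time_labels` and `values`.
#' @export
expression_matrix <- function(values, gene_ids, time_labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  time_labels <- as.character(time_labels)
  if (nrow(values) < 1L)
    stop("expression matrix must contain at least one gene", call. = FALSE)
  if (ncol(values) < 2L)
    stop("expression matrix must contain at least two time points", call. = FALSE)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match the number of rows", call. = FALSE)
  if (length(time_labels) != ncol(values))
    stop("time_labels length does not match the number of columns", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene identifiers must be unique", call. = FALSE)
  if (anyDuplicated(time_labels))
    stop("time-point labels must be unique", call. = FALSE)
  dimnames(values) <- list(gene_ids, time_labels)
  structure(
    list(gene_ids = gene_ids, time_labels = time_labels, values = values),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<%s> %d genes x %d time points (%s ... %s)\n",
    class(x)[1L], length(x$gene_ids), length(x$time_labels),
    x$time_labels[1L], x$time_labels[length(x$time_labels)]
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors; each element is the member
#'   identifiers of one gene set.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty string when absent).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L)
    stop("gene-set collection must contain at least one set", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every gene set must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate gene-set name: '%s'", nm[duplicated(nm)][1L]),
         call. = FALSE)
  sets <- lapply(sets, as.character)
  sizes <- vapply(sets, length, integer(1L))
  if (any(sizes == 0L))
    stop(sprintf("gene set '%s' has no members", nm[sizes == 0L][1L]),
         call. = FALSE)
  if (any(vapply(sets, function(m) any(!nzchar(m)), logical(1L))))
    stop("gene-set members must be non-empty strings", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(
    list(sets = sets, descriptions = stats::setNames(descriptions, nm)),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x$sets, length, integer(1L))
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x$sets), min(sz), max(sz)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# Normalize gene identifiers for matrix <-> gene-set matching. Microarray
# probe annotations are case-inconsistent, so matching is case-insensitive
# (after whitespace trimming) unless turned off.
normalize_ids <- function(ids, case_insensitive = TRUE) {
  ids <- trimws(ids)
  if (case_insensitive) ids <- tolower(ids)
  ids
}

# Temporal profile: the per-time-point mean of a group of scaled genes.
new_profile <- function(values, time_labels, n_genes) {
  structure(
    list(time_labels = as.character(time_labels),
         values = stats::setNames(as.numeric(values), time_labels),
         n_genes = as.integer(n_genes)),
    class = "expr_profile"
  )
}

#' @export
print.expr_profile <- function(x, digits = 3L, ...) {
  cat(sprintf("<expr_profile> mean of %d gene(s) over %d time points\n",
              x$n_genes, length(x$values)))
  print(round(x$values, digits))
  invisible(x)
}

# Coerce a profile or bare numeric vector to its numeric values.
profile_values <- function(x) {
  if (inherits(x, "expr_profile")) x$values else as.numeric(x)
}
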