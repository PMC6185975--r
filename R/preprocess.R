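#' Filter genes unusable by the scaling step
#'
#' Removes genes whose temporal profile cannot be z-scaled: by default genes
#' with any missing value and genes with zero variance across the time
#' course. Missing values are dropped rather than imputed — the distance
#' statistic is defined on complete profiles and imputation would add
#' untestable assumptions. Counts removed per reason are reported via
#' [message()] and attached as the `"filter_log"` attribute.
#'
#' @param x an [expression_matrix()].
#' @param drop_missing remove genes with any `NA` value.
#' @param drop_zero_variance remove genes constant across time points.
#' @return The filtered [expression_matrix()]; errors if no gene survives.
#' @export
filter_genes <- function(x, drop_missing = TRUE, drop_zero_variance = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  has_na <- apply(v, 1L, anyNA)
  rm_missing <- drop_missing & has_na
  # a row with NAs is judged on missingness only; variance needs complete data
  rng <- suppressWarnings(apply(v, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) 0 else max(r) - min(r)
  }))
  rm_const <- drop_zero_variance & !has_na & (rng == 0)
  keep <- !(rm_missing | rm_const)
  log <- c(missing = sum(rm_missing), zero_variance = sum(rm_const))
  if (sum(log) > 0L)
    message(sprintf("filtered %d gene(s): %d with missing values, %d with zero variance",
                    sum(log), log[["missing"]], log[["zero_variance"]]))
  if (!any(keep))
    stop("no genes remain after filtering", call. = FALSE)
  out <- expression_matrix(v[keep, , drop = FALSE], x$gene_ids[keep],
                           x$time_labels)
  attr(out, "filter_log") <- log
  out
}

#' Z-scale each gene's temporal profile
#'
#' Transforms every row to `(x - mean(x)) / sd(x)` so each gene's profile has
#' mean zero and standard deviation one across the time course. This puts
#' genes measured at different absolute expression levels on a common scale
#' before profiles are averaged and compared.
#'
#' @param x an [expression_matrix()] with no missing values and no constant
#'   rows (see [filter_genes()]).
#' @param sd_denominator `"sample"` (divisor `M - 1`, the default) or
#'   `"population"` (divisor `M`).
#' @return A `scaled_matrix` (subclass of `expression_matrix`) whose rows
#'   all have mean 0 and the stated unit standard deviation.
#' @export
scale_rows <- function(x, sd_denominator = c("sample", "population")) {
  stopifnot(inherits(x, "expression_matrix"))
  sd_denominator <- match.arg(sd_denominator)
  v <- x$values
  if (anyNA(v))
    stop("scale_rows requires a complete matrix; run filter_genes first",
         call. = FALSE)
  m <- ncol(v)
  mu <- rowMeans(v)
  cv <- v - mu
  ss <- rowSums(cv^2)
  denom <- if (sd_denominator == "sample") m - 1L else m
  sdv <- sqrt(ss / denom)
  if (any(sdv == 0))
    stop(sprintf("gene '%s' is constant across time points and cannot be scaled",
                 x$gene_ids[which(sdv == 0)[1L]]), call. = FALSE)
  out <- expression_matrix(cv / sdv, x$gene_ids, x$time_labels)
  class(out) <- c("scaled_matrix", class(out))
  attr(out, "sd_denominator") <- sd_denominator
  out
}

#' Background expression profile
#'
#' The per-time-point mean over all scaled genes: the reference profile
#' against which each gene set's mean profile is compared. Because every
#' scaled row has mean zero, the background values sum to zero across time.
#'
#' @param scaled a `scaled_matrix` from [scale_rows()].
#' @return An `expr_profile` with `n_genes` equal to the universe size.
#' @export
background_profile <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  new_profile(colMeans(scaled$values), scaled$time_labels,
              nrow(scaled$values))
}

#' Mean scaled profile of a gene set
#'
#' Averages the scaled rows of the set members present in the matrix. Sets
#' whose overlap with the measured universe is below `min_overlap` are not
#' testable: the function reports this via [message()] and returns `NULL`
#' (a skip signal, not an error).
#'
#' @param scaled a `scaled_matrix`.
#' @param members character vector of member gene identifiers.
#' @param min_overlap minimum number of members that must be present
#'   (default 3; single-gene "sets" are degenerate for a set-level statistic).
#' @param case_insensitive match identifiers case-insensitively after
#'   trimming (must mirror how the matrix was read).
#' @return An `expr_profile` over the overlapping genes, or `NULL` when the
#'   overlap is below `min_overlap`.
#' @export
set_profile <- function(scaled, members, min_overlap = 3L,
                        case_insensitive = TRUE) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  idx <- set_overlap_idx(scaled, members, case_insensitive)
  if (length(idx) < min_overlap) {
    message(sprintf(
      "set not testable: %d of %d member(s) present, minimum overlap is %d",
      length(idx), length(members), min_overlap))
    return(NULL)
  }
  new_profile(colMeans(scaled$values[idx, , drop = FALSE]),
              scaled$time_labels, length(idx))
}

# Row indices of the set members present in the (scaled) matrix.
set_overlap_idx <- function(scaled, members, case_insensitive = TRUE) {
  ids <- normalize_ids(scaled$gene_ids, case_insensitive)
  mem <- unique(normalize_ids(members, case_insensitive))
  which(ids %in% mem)
}
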