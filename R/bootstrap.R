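#' Analysis configuration
#'
#' Bundles the tuning parameters of the bootstrap gene-set analysis.
#'
#' @param B number of null resamples (default 1000).
#' @param seed integer seed making the whole run deterministic; each set's
#'   null uses a seed derived from `(seed, set name)` so per-set nulls are
#'   independent and unaffected by adding or removing other sets.
#' @param sampling `"without_replacement"` (default: a random gene set is a
#'   subset of the universe, no duplicate genes) or `"with_replacement"`.
#' @param adjust_method multiple-testing adjustment: `"BH"`
#'   (Benjamini-Hochberg false discovery rate, default), `"holm"` or
#'   `"bonferroni"`.
#' @param alpha significance threshold on the adjusted p-value (default 0.05).
#' @param min_overlap minimum members present for a set to be testable
#'   (default 3).
#' @param sd_denominator row-scaling divisor, see [scale_rows()].
#' @param case_insensitive identifier matching convention, see
#'   [set_profile()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(B = 1000L, seed = 1L,
                            sampling = c("without_replacement",
                                         "with_replacement"),
                            adjust_method = c("BH", "holm", "bonferroni"),
                            alpha = 0.05, min_overlap = 3L,
                            sd_denominator = c("sample", "population"),
                            case_insensitive = TRUE) {
  sampling <- match.arg(sampling)
  adjust_method <- match.arg(adjust_method)
  sd_denominator <- match.arg(sd_denominator)
  B <- as.integer(B)
  if (is.na(B) || B < 1L)
    stop("B must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L)
    stop("min_overlap must be a positive integer", call. = FALSE)
  structure(
    list(B = B, seed = as.integer(seed), sampling = sampling,
         adjust_method = adjust_method, alpha = alpha,
         min_overlap = min_overlap, sd_denominator = sd_denominator,
         case_insensitive = case_insensitive),
    class = "analysis_config"
  )
}

#' Euclidean distance between a set profile and the background
#'
#' The dynamic-expression statistic `d`: the Euclidean distance between a
#' gene set's mean scaled profile and the background (all-gene mean) profile
#' over the time course. Large `d` means the set's temporal behaviour
#' departs from the transcriptome-wide average.
#'
#' @param set_prof,background `expr_profile` objects (or bare numeric
#'   vectors) sharing the same time grid.
#' @return A non-negative scalar.
#' @export
distance_to_background <- function(set_prof, background) {
  if (inherits(set_prof, "expr_profile") &&
      inherits(background, "expr_profile") &&
      !identical(set_prof$time_labels, background$time_labels))
    stop("profiles are defined on different time grids", call. = FALSE)
  a <- profile_values(set_prof)
  b <- profile_values(background)
  if (length(a) != length(b))
    stop("profiles have different lengths", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Bootstrap null distribution of the distance statistic
#'
#' Draws `B` random gene sets of the given size from the full scaled
#' universe (members of the observed set are not excluded), computes each
#' draw's mean profile and its Euclidean distance to the fixed background
#' profile. The background is computed once from the scaled matrix and never
#' recomputed per resample.
#'
#' @param scaled a `scaled_matrix`.
#' @param set_size number of genes per resample (use the observed set's
#'   overlap with the matrix).
#' @param config an [analysis_config()]; `B`, `sampling` and `seed` are used.
#' @param seed optional override of `config$seed` (e.g. a per-set derived
#'   seed).
#' @param background optional precomputed [background_profile()].
#' @return An object of class `null_distribution` with fields `distances`
#'   (length `B`), `set_size`, `seed` and `sampling_mode`.
#' @export
sample_null <- function(scaled, set_size, config = analysis_config(),
                        seed = config$seed, background = NULL) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  n <- nrow(scaled$values)
  set_size <- as.integer(set_size)
  if (set_size < 1L)
    stop("set_size must be at least 1", call. = FALSE)
  replace <- config$sampling == "with_replacement"
  if (!replace && set_size > n)
    stop(sprintf("set_size %d exceeds the %d-gene universe when sampling without replacement",
                 set_size, n), call. = FALSE)
  if (is.null(background)) background <- background_profile(scaled)
  bg <- profile_values(background)
  v <- scaled$values
  m <- ncol(v)
  distances <- with_seed(seed, {
    vapply(seq_len(config$B), function(b) {
      idx <- sample.int(n, set_size, replace = replace)
      prof <- .colMeans(v[idx, , drop = FALSE], set_size, m)
      sqrt(sum((prof - bg)^2))
    }, numeric(1L))
  })
  structure(
    list(distances = distances, set_size = set_size, seed = as.integer(seed),
         sampling_mode = config$sampling),
    class = "null_distribution"
  )
}

#' Plus-one-corrected empirical p-value
#'
#' Computes `(sum(d0 > d) + 1) / (B + 1)`: the fraction of null distances
#' strictly exceeding the observed statistic, with the plus-one correction
#' that keeps the p-value positive. Ties between a null distance and `d` do
#' not count as exceedances (the exceedance indicator is 1 only for a
#' strictly positive difference).
#'
#' @param d observed distance statistic.
#' @param null a `null_distribution` from [sample_null()] (a bare numeric
#'   vector of null distances is also accepted).
#' @return A p-value in `[1/(B+1), 1]`.
#' @export
p_value <- function(d, null) {
  d0 <- if (inherits(null, "null_distribution")) null$distances else
    as.numeric(null)
  if (length(d0) == 0L)
    stop("null distribution is empty", call. = FALSE)
  (sum(d0 > d) + 1) / (length(d0) + 1)
}

#' Exact enumeration p-value (verification oracle)
#'
#' For small universes, enumerates every size-`|S|` subset of the scaled
#' matrix, computes its distance to the background, and returns the
#' plus-one-corrected exceedance fraction over all `choose(N, |S|)` subsets.
#' Intended as an independent check of the sampled null on toy problems; it
#' refuses universes beyond `max_subsets`.
#'
#' @param scaled a `scaled_matrix`.
#' @param members member identifiers of the observed set.
#' @param max_subsets refusal threshold on `choose(N, |S|)` (default 1e5).
#' @param case_insensitive identifier matching convention.
#' @return `(K + 1) / (choose(N, |S|) + 1)` where `K` counts subsets with
#'   distance strictly greater than the observed set's.
#' @export
exact_p <- function(scaled, members, max_subsets = 1e5,
                    case_insensitive = TRUE) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  idx <- set_overlap_idx(scaled, members, case_insensitive)
  k <- length(idx)
  if (k < 1L)
    stop("no set members are present in the matrix", call. = FALSE)
  n <- nrow(scaled$values)
  n_sub <- choose(n, k)
  if (n_sub > max_subsets)
    stop(sprintf(
      "choose(%d, %d) = %.0f subsets exceeds the enumeration cap (%g); use sample_null",
      n, k, n_sub, max_subsets), call. = FALSE)
  bg <- colMeans(scaled$values)
  v <- scaled$values
  m <- ncol(v)
  d_obs <- sqrt(sum((.colMeans(v[idx, , drop = FALSE], k, m) - bg)^2))
  combos <- utils::combn(n, k)
  d_all <- apply(combos, 2L, function(ix)
    sqrt(sum((.colMeans(v[ix, , drop = FALSE], k, m) - bg)^2)))
  (sum(d_all > d_obs) + 1) / (n_sub + 1)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the methods exposed by
#' the pipeline, with input validation: raw p-values must lie in `(0, 1]`
#' (empirical plus-one-corrected p-values are never zero).
#'
#' @param p_raw numeric vector of raw p-values in `(0, 1]`.
#' @param method `"BH"` (default), `"holm"` or `"bonferroni"`.
#' @return Adjusted p-values in the input order, clipped to at most 1.
#' @export
adjust_pvalues <- function(p_raw, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (length(p_raw) == 0L) return(numeric(0L))
  if (any(is.na(p_raw)) || any(p_raw <= 0) || any(p_raw > 1))
    stop("raw p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_raw, method = method)
}

#' Run the full bootstrap gene-set analysis
#'
#' The end-to-end pipeline: filter unusable genes, z-scale each gene's
#' profile, compute the background profile, and for every testable gene set
#' compute its mean profile, the distance statistic `d`, a size-matched
#' bootstrap null and the empirical p-value; finally adjust p-values across
#' the testable sets (untestable sets contribute no hypothesis and are
#' carried through with `testable = FALSE`).
#'
#' @param exprs an [expression_matrix()].
#' @param sets a [gene_set_collection()].
#' @param config an [analysis_config()].
#' @return An object of class `bootgsa_result`: a list with `table` (one row
#'   per input set: `set_name`, `set_size`, `overlap`, `d`, `p_raw`, `p_adj`,
#'   `significant`, `testable`), `profiles` (testable sets x time points
#'   matrix of scaled mean profiles), `background`, `time_labels`, `config`
#'   and `counts` (genes parsed / retained, sets tested).
#' @export
run_analysis <- function(exprs, sets, config = analysis_config()) {
  stopifnot(inherits(exprs, "expression_matrix"),
            inherits(sets, "gene_set_collection"),
            inherits(config, "analysis_config"))
  n_parsed <- nrow(exprs$values)
  filtered <- filter_genes(exprs)
  scaled <- scale_rows(filtered, config$sd_denominator)
  background <- background_profile(scaled)

  nms <- names(sets$sets)
  n_sets <- length(nms)
  overlap <- integer(n_sets)
  d <- p_raw <- rep(NA_real_, n_sets)
  testable <- logical(n_sets)
  profiles <- matrix(NA_real_, nrow = n_sets, ncol = length(scaled$time_labels),
                     dimnames = list(nms, scaled$time_labels))
  for (i in seq_len(n_sets)) {
    idx <- set_overlap_idx(scaled, sets$sets[[i]], config$case_insensitive)
    overlap[i] <- length(idx)
    if (length(idx) < config$min_overlap) next
    testable[i] <- TRUE
    prof <- new_profile(colMeans(scaled$values[idx, , drop = FALSE]),
                        scaled$time_labels, length(idx))
    profiles[i, ] <- prof$values
    d[i] <- distance_to_background(prof, background)
    null <- sample_null(scaled, length(idx), config,
                        seed = derive_seed(config$seed, nms[i]),
                        background = background)
    p_raw[i] <- p_value(d[i], null)
  }
  p_adj <- rep(NA_real_, n_sets)
  p_adj[testable] <- adjust_pvalues(p_raw[testable], config$adjust_method)

  tab <- data.frame(
    set_name = nms,
    set_size = vapply(sets$sets, length, integer(1L)),
    overlap = overlap,
    d = d,
    p_raw = p_raw,
    p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < config$alpha,
    testable = testable,
    row.names = NULL
  )
  structure(
    list(table = tab,
         profiles = profiles[testable, , drop = FALSE],
         background = background,
         time_labels = scaled$time_labels,
         config = config,
         counts = c(genes_parsed = n_parsed,
                    genes_retained = nrow(scaled$values),
                    sets_total = n_sets,
                    sets_testable = sum(testable))),
    class = "bootgsa_result"
  )
}

#' @export
print.bootgsa_result <- function(x, ...) {
  cat(sprintf(
    "<bootgsa_result> %d sets (%d testable) over %d genes, B = %d\n",
    x$counts[["sets_total"]], x$counts[["sets_testable"]],
    x$counts[["genes_retained"]], x$config$B))
  sig <- x$table[x$table$significant %in% TRUE, , drop = FALSE]
  cat(sprintf("significant at adjusted p < %g: %d set(s)\n",
              x$config$alpha, nrow(sig)))
  if (nrow(sig) > 0L)
    print(sig[order(sig$p_raw, sig$set_name),
              c("set_name", "overlap", "d", "p_raw", "p_adj")],
          row.names = FALSE)
  invisible(x)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 31-bit seed derived from the global seed and a set name, so each
# set's null is reproducible and unaffected by the rest of the collection.
derive_seed <- function(seed, name) {
  p <- 2147483647
  h <- 5381
  for (c in utf8ToInt(paste(seed, name, sep = "\r")))
    h <- (h * 33 + c) %% p
  as.integer(h)
}
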