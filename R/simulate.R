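#' Default injury time-course grid
#'
#' The nine sampling times of a heart-injury regeneration time course, from
#' two hours to thirty-five days postinjury.
#' @return Character vector of 9 time labels.
#' @export
default_time_labels <- function() {
  c("2h", "6h", "24h", "48h", "4d", "7d", "14d", "21d", "35d")
}

#' Specify one synthetic gene set
#'
#' @param name set name.
#' @param size number of member genes.
#' @param phase temporal behaviour shared by the members:
#'   `"early_transient"` (induced over the first third of the time course,
#'   suppressed after — the inflammatory-response shape),
#'   `"late_sustained"` (flat induction from the midpoint of the time course
#'   on — the sustained-signaling shape) or `"null"` (no shared dynamics).
#' @param effect non-negative effect size: the amplitude of the shared
#'   template relative to the per-gene noise standard deviation. Forced to 0
#'   for `"null"` sets.
#' @return A list describing the set.
#' @export
set_spec <- function(name, size, phase = c("null", "early_transient",
                                           "late_sustained"),
                     effect = 0) {
  phase <- match.arg(phase)
  size <- as.integer(size)
  if (is.na(size) || size < 1L)
    stop("set size must be a positive integer", call. = FALSE)
  if (!is.numeric(effect) || effect < 0)
    stop("effect size must be non-negative", call. = FALSE)
  if (phase == "null") effect <- 0
  list(name = as.character(name), size = size, phase = phase,
       effect = as.numeric(effect))
}

#' Synthetic time-course configuration
#'
#' Parameters of the synthetic expression generator. The defaults emulate
#' the structure of a deposited microarray injury time course — thousands of
#' genes over the nine-point grid of [default_time_labels()] — scaled down
#' to 2,000 genes so simulation studies stay fast; the repository-scale
#' 18,560 genes is a configuration choice, not a different code path.
#'
#' @param n_genes universe size (default 2000).
#' @param time_labels ordered time-point labels (default the 9-point grid).
#' @param noise_sd per-gene, per-time-point noise standard deviation
#'   (default 1.0).
#' @param baseline_sd standard deviation of the per-gene baseline offset
#'   (default 2.0), emulating gene-to-gene differences in absolute
#'   expression level.
#' @param scale_range range of the per-gene multiplicative scale (default
#'   `c(0.5, 2)`), emulating probe-level magnitude differences; both baseline
#'   and scale are absorbed by the pipeline's row z-scaling.
#' @param sets list of [set_spec()] entries (default: twenty null sets of
#'   size 50).
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             time_labels = default_time_labels(),
                             noise_sd = 1.0,
                             baseline_sd = 2.0,
                             scale_range = c(0.5, 2),
                             sets = default_null_sets(),
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 2L)
    stop("n_genes must be at least 2", call. = FALSE)
  time_labels <- as.character(time_labels)
  if (length(time_labels) < 2L || anyDuplicated(time_labels))
    stop("time_labels must be at least 2 unique labels", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1L] > scale_range[2L])
    stop("scale_range must be an increasing pair of positive values",
         call. = FALSE)
  if (length(sets) == 0L)
    stop("at least one gene set must be specified", call. = FALSE)
  sets <- lapply(sets, function(s)
    do.call(set_spec, s[c("name", "size", "phase", "effect")]))
  nms <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("synthetic set names must be unique", call. = FALSE)
  sizes <- vapply(sets, `[[`, integer(1L), "size")
  if (any(sizes > n_genes))
    stop("a requested set is larger than the gene universe", call. = FALSE)
  non_null <- vapply(sets, `[[`, character(1L), "phase") != "null"
  if (sum(sizes[non_null]) > n_genes)
    stop("disjoint non-null sets exceed the gene universe", call. = FALSE)
  structure(
    list(n_genes = n_genes, time_labels = time_labels, noise_sd = noise_sd,
         baseline_sd = baseline_sd, scale_range = as.numeric(scale_range),
         sets = sets, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

default_null_sets <- function(n = 20L, size = 50L) {
  lapply(seq_len(n), function(i)
    set_spec(sprintf("null_set_%02d", i), size, "null", 0))
}

#' Phase templates for the synthetic time course
#'
#' Builds the shared temporal shapes injected into "dynamic" sets:
#' `early_transient` is positive over the first third of the time points and
#' non-positive afterwards; `late_sustained` is non-positive early and
#' positive and flat from the midpoint of the time course on. Each non-null
#' template is mean-centered across time and scaled to unit Euclidean norm,
#' so the `effect` parameter of [set_spec()] is the template amplitude in
#' noise-standard-deviation units. The `null` template is the zero vector.
#'
#' @param time_labels ordered time-point labels (length at least 2).
#' @return Named list of numeric vectors (`early_transient`,
#'   `late_sustained`, `null`), each of the grid's length.
#' @export
make_templates <- function(time_labels = default_time_labels()) {
  m <- length(time_labels)
  if (m < 2L)
    stop("at least two time points are required", call. = FALSE)
  early_on <- seq_len(max(1L, ceiling(m / 3)))
  late_on <- seq.int(floor(m / 2) + 1L, m)
  shape <- function(on) {
    raw <- rep(0, m)
    raw[on] <- 1
    centered <- raw - mean(raw)
    centered / sqrt(sum(centered^2))
  }
  out <- list(
    early_transient = shape(early_on),
    late_sustained = shape(late_on),
    null = rep(0, m)
  )
  lapply(out, stats::setNames, time_labels)
}

#' Simulate a synthetic injury time-course dataset
#'
#' Generates an expression matrix, a gene-set collection and ground-truth
#' phase labels under the model
#' `x[g, t] = baseline[g] + scale[g] * (effect[g] * template[g, t] + eps[g, t])`
#' with independent Gaussian noise `eps ~ N(0, noise_sd^2)`. Members of
#' non-null sets share their phase template (injected before the per-gene
#' baseline/scale transform, so detectability is governed by the
#' effect-to-noise ratio, not raw units); all other genes are pure noise.
#' Non-null sets are assigned disjoint member lists so truth labels are
#' unambiguous; null sets are drawn independently and may overlap.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with fields `matrix`
#'   (an [expression_matrix()]), `sets` (a [gene_set_collection()]) and
#'   `truth` (named character vector, set name to phase).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  tl <- config$time_labels
  m <- length(tl)
  templates <- make_templates(tl)
  with_seed(config$seed, {
    gene_ids <- sprintf("g%06d", seq_len(n))
    baseline <- stats::rnorm(n, 0, config$baseline_sd)
    scale_g <- stats::runif(n, config$scale_range[1L], config$scale_range[2L])

    phases <- vapply(config$sets, `[[`, character(1L), "phase")
    effects <- vapply(config$sets, `[[`, numeric(1L), "effect")
    sizes <- vapply(config$sets, `[[`, integer(1L), "size")
    nms <- vapply(config$sets, `[[`, character(1L), "name")

    signal <- matrix(0, nrow = n, ncol = m)
    members <- vector("list", length(config$sets))
    names(members) <- nms
    # disjoint assignment pool for sets carrying a shared template
    pool <- sample.int(n)
    taken <- 0L
    for (i in seq_along(config$sets)) {
      if (phases[i] == "null") {
        members[[i]] <- gene_ids[sample.int(n, sizes[i])]
      } else {
        idx <- pool[(taken + 1L):(taken + sizes[i])]
        taken <- taken + sizes[i]
        members[[i]] <- gene_ids[idx]
        signal[idx, ] <- matrix(effects[i] * templates[[phases[i]]],
                                nrow = sizes[i], ncol = m, byrow = TRUE)
      }
    }
    eps <- matrix(stats::rnorm(n * m, 0, config$noise_sd), nrow = n, ncol = m)
    values <- baseline + scale_g * (signal + eps)
    structure(
      list(matrix = expression_matrix(values, gene_ids, tl),
           sets = gene_set_collection(
             members, sprintf("synthetic %s set", phases)),
           truth = stats::setNames(phases, nms)),
      class = "synthetic_dataset"
    )
  })
}

#' Simulate a structure-free (null) dataset
#'
#' Convenience wrapper over [simulate_dataset()] that forces every set's
#' phase to `"null"` (effect 0), keeping names and sizes. Used for type-I
#' error calibration.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_dataset` with no injected structure.
#' @export
simulate_null_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  config$sets <- lapply(config$sets, function(s)
    set_spec(s$name, s$size, "null", 0))
  simulate_dataset(config)
}

#' Write a synthetic dataset to disk
#'
#' Writes `matrix.tsv` (expression TSV), `sets.gmt` (gene sets) and
#' `truth.tsv` (set name, phase, size) into a directory, so the file-based
#' pipeline can be exercised end to end.
#'
#' @param dataset a `synthetic_dataset` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             sets = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(dataset$matrix, paths[["matrix"]])
  write_gmt(dataset$sets, paths[["sets"]])
  truth <- data.frame(
    set_name = names(dataset$truth),
    phase = unname(dataset$truth),
    size = vapply(dataset$sets$sets, length, integer(1L))[names(dataset$truth)]
  )
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
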