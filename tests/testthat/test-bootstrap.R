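test_that("the distance statistic is the Euclidean norm of the profile difference", {
  bg <- rep(0, 9)
  expect_identical(distance_to_background(bg, bg), 0)
  expect_identical(distance_to_background(c(3, 4, rep(0, 7)), bg), 5)
  # brute-force elementwise oracle on random pairs
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(9); b <- rnorm(9)
    acc <- 0
    for (t in seq_along(a)) acc <- acc + (a[t] - b[t]) * (a[t] - b[t])
    expect_equal(distance_to_background(a, b), sqrt(acc), tolerance = 1e-12)
  }
  s <- toy_scaled()
  p1 <- set_profile(s, s$gene_ids[1:3])
  bgp <- background_profile(s)
  expect_gte(distance_to_background(p1, bgp), 0)
  short <- bgp; short$values <- bgp$values[1:2]; short$time_labels <- bgp$time_labels[1:2]
  expect_error(distance_to_background(p1, short), "time grids")
  expect_error(distance_to_background(c(1, 2), c(1, 2, 3)), "lengths")
})

test_that("null sampling is seeded, size-aware and degenerates correctly", {
  s <- toy_scaled(n = 12L, m = 5L)
  cfg <- analysis_config(B = 50L, seed = 99L)
  n1 <- sample_null(s, 4L, cfg)
  n2 <- sample_null(s, 4L, cfg)
  expect_identical(n1$distances, n2$distances)
  expect_length(n1$distances, 50L)
  expect_true(all(n1$distances >= 0))
  expect_false(identical(n1$distances,
                         sample_null(s, 4L, cfg, seed = 100L)$distances))
  # sampling the whole universe without replacement always returns the background
  full <- sample_null(s, 12L, cfg)
  expect_equal(full$distances, rep(0, 50L), tolerance = 1e-12)
  expect_error(sample_null(s, 13L, cfg), "exceeds")
  # with replacement the full-size draw is not degenerate
  wr <- analysis_config(B = 50L, seed = 99L, sampling = "with_replacement")
  expect_gt(max(sample_null(s, 13L, wr)$distances), 0)
})

test_that("sampled null matches the exhaustive subset distribution on a toy universe", {
  # 6-gene universe, sets of 2: only 15 subsets, enumerable exactly
  s <- toy_scaled(n = 6L, m = 4L, seed = 2L)
  bg <- colMeans(s$values)
  combos <- combn(6L, 2L)
  d_exact <- apply(combos, 2L, function(ix)
    sqrt(sum((colMeans(s$values[ix, , drop = FALSE]) - bg)^2)))
  null <- sample_null(s, 2L, analysis_config(B = 1000L, seed = 8L))
  ks <- suppressWarnings(
    ks.test(null$distances, ecdf(d_exact))$statistic)
  # uniform sampling of 15 atoms: KS distance bounded by Monte-Carlo error
  expect_lt(unname(ks), 3 * sqrt(log(2 / 0.01) / (2 * 1000)) + 1 / 15)
})

test_that("the plus-one-corrected p-value follows the strict-exceedance formula", {
  null <- structure(list(distances = rep(1, 1000), set_size = 3L,
                         seed = 1L, sampling_mode = "without_replacement"),
                    class = "null_distribution")
  expect_identical(p_value(2, null), 1 / 1001)    # nothing exceeds
  expect_identical(p_value(0.5, null), 1001 / 1001) # everything exceeds
  expect_identical(p_value(1, null), 1 / 1001)    # ties never count
  mixed <- c(rep(2, 500), rep(0.5, 500))
  expect_identical(p_value(1, mixed), 501 / 1001)
  expect_error(p_value(1, numeric(0)), "empty")
  # monotone nonincreasing in d over a fixed null sample
  set.seed(14)
  d0 <- runif(200)
  ds <- sort(runif(50))
  ps <- vapply(ds, p_value, numeric(1), null = d0)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 1 / 201 & ps <= 1))
})

test_that("the enumeration oracle obeys its combinatorial contracts", {
  s <- toy_scaled(n = 6L, m = 4L, seed = 2L)
  # denominator is C(6,2)+1 = 16
  p <- exact_p(s, s$gene_ids[1:2])
  expect_true(p %in% ((1:16) / 16))
  # the whole universe is its own only subset: K = 0, p = 1/2
  expect_identical(exact_p(s, s$gene_ids), 1 / 2)
  expect_error(exact_p(s, s$gene_ids[1:3], max_subsets = 10), "cap")
  expect_error(exact_p(s, c("nope1", "nope2")), "no set members")
})

test_that("bootstrap p-values agree with the enumeration oracle", {
  # random instances sized so the oracle's +1/(C+1) correction is negligible
  # next to the Monte-Carlo standard error of B = 10^4 resamples
  set.seed(1)
  for (i in 1:20) {
    n <- sample(18:21, 1L); k <- 3L
    s <- scale_rows(expression_matrix(matrix(rnorm(n * 5), n),
                                      sprintf("g%02d", 1:n), paste0("t", 1:5)))
    members <- s$gene_ids[sample(n, k)]
    pe <- exact_p(s, members)
    d <- distance_to_background(set_profile(s, members),
                                background_profile(s))
    pb <- p_value(d, sample_null(s, k, analysis_config(B = 10000L, seed = i)))
    expect_lt(abs(pb - pe), 3 * sqrt(pe * (1 - pe) / 10000) + 1e-12)
  }
})

test_that("p-value adjustment validates input and applies the step-up rule", {
  expect_identical(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  p <- c(0.001, 0.5, 0.02, 1)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_identical(adjust_pvalues(numeric(0)), numeric(0))
  expect_error(adjust_pvalues(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(adjust_pvalues(1.2), "\\(0, 1\\]")
})

test_that("run_analysis is deterministic and ranks an injected set first", {
  ds <- simulate_dataset(synthetic_config(
    n_genes = 400L, sets = benchmark_sets(6L, size = 20L, effect = 3), seed = 31L))
  cfg <- analysis_config(B = 300L, seed = 31L)
  r1 <- run_analysis(ds$matrix, ds$sets, cfg)
  r2 <- run_analysis(ds$matrix, ds$sets, cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$profiles, r2$profiles)
  expect_identical(r1$table$set_name[which.min(r1$table$p_raw)], "injected")
  expect_true(all(r1$table$p_adj >= r1$table$p_raw))
  expect_true(all(r1$table$p_raw >= 1 / (cfg$B + 1)))
  # per-set nulls keyed to set names: removing another set leaves results intact
  drop1 <- gene_set_collection(ds$sets$sets[-3L], ds$sets$descriptions[-3L])
  r3 <- run_analysis(ds$matrix, drop1, cfg)
  kept <- match(r3$table$set_name, r1$table$set_name)
  expect_equal(r3$table$p_raw, r1$table$p_raw[kept], tolerance = 1e-12)
})

test_that("untestable sets are carried through without a hypothesis", {
  ds <- simulate_dataset(synthetic_config(
    n_genes = 200L, sets = benchmark_sets(3L, size = 15L), seed = 6L))
  sets <- ds$sets
  sets$sets$tiny <- c(sets$sets$injected[1:2], "unmeasured_gene")
  sets$descriptions <- c(sets$descriptions, tiny = "below overlap floor")
  res <- suppressMessages(
    run_analysis(ds$matrix, sets, analysis_config(B = 200L, seed = 6L)))
  row <- res$table[res$table$set_name == "tiny", ]
  expect_false(row$testable)
  expect_true(is.na(row$p_raw) && is.na(row$p_adj))
  expect_identical(row$overlap, 2L)
  expect_false("tiny" %in% rownames(res$profiles))
  # multiplicity counts testable sets only
  testable <- res$table[res$table$testable, ]
  expect_equal(testable$p_adj,
               adjust_pvalues(testable$p_raw), tolerance = 1e-12)
  expect_identical(res$counts[["sets_testable"]],
                   sum(res$table$testable))
})
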