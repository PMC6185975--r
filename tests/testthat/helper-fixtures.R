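# In-code fixtures shared across test files.

# Small deterministic expression matrix (already complete, non-constant rows).
toy_matrix <- function(n = 5L, m = 4L, seed = 11L) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n * m), n, m),
                    sprintf("gene%02d", seq_len(n)),
                    paste0("t", seq_len(m)))
}

toy_scaled <- function(n = 5L, m = 4L, seed = 11L) {
  scale_rows(toy_matrix(n, m, seed))
}

# Write a well-formed expression TSV; returns the path.
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

expr_tsv_lines <- function() {
  c("gene_id\tt1\tt2\tt3",
    "g1\t1\t2\t3",
    "g2\t0.5\tNA\t1.5",
    "g3\t-1\t0\t1")
}

gmt_lines <- function() {
  c("HH\thedgehog pathway\tshh\tptc1\tsmo",
    "WNT\twnt pathway\twnt1\twnt3a\tfzd1\tlrp5")
}

# One injected late-sustained set among null sets, mirroring the benchmark
# layout used throughout the simulation tests.
benchmark_sets <- function(n_null = 19L, size = 50L, effect = 3) {
  c(list(set_spec("injected", size, "late_sustained", effect)),
    lapply(seq_len(n_null), function(i)
      set_spec(sprintf("null_%02d", i), size, "null")))
}
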