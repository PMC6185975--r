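# bootGSA

Bootstrap gene-set analysis of time-course expression dynamics.

## What it is for

Injury and regeneration studies often profile a tissue at a handful of
time points — e.g. a regenerating newt heart sampled from 2 hours to 35
days postinjury — and ask which pathways respond *coherently* over time,
not just which single genes move. bootGSA answers that question at the
gene-set level for anyone with a genes × time-points expression matrix
(TSV) and a pathway collection (GMT).

## The statistic

Each gene's temporal profile is z-scaled across the `M` time points. For a
gene set `S` the statistic is the Euclidean distance between the set's
mean scaled profile and the background profile (the mean over all genes):

    d(S) = sqrt( sum_t ( mean_{g in S} x_gt  -  mean_{g} x_gt )^2 )

A null distribution `d0` is built by drawing `B` (default 1000) random
size-matched gene sets from the same universe; the empirical p-value is
the plus-one-corrected strict exceedance fraction

    p = ( #{ b : d0_b > d } + 1 ) / ( B + 1 )

and p-values are adjusted across sets by Benjamini–Hochberg FDR, with sets
reported at adjusted p < 0.05. A synthetic time-course generator with
ground-truth "early transient" and "late sustained" dynamic sets makes the
whole pipeline testable without any download, and `exact_p()` provides an
exhaustive-enumeration oracle on small universes.

## Worked example

```r
library(bootGSA)
sets <- c(list(set_spec("hh_like", 50, "late_sustained", effect = 3)),
          lapply(1:19, function(i) set_spec(sprintf("null_%02d", i), 50, "null")))
ds  <- simulate_dataset(synthetic_config(n_genes = 2000, sets = sets, seed = 42))
res <- run_analysis(ds$matrix, ds$sets, analysis_config(B = 1000, seed = 42))
res
#> <bootgsa_result> 20 sets (20 testable) over 2000 genes, B = 1000
#> significant at adjusted p < 0.05: 1 set(s)
#>  set_name overlap        d       p_raw      p_adj
#>   hh_like      50 1.988722 0.000999001 0.01998002
round(profile_report(res, significant_only = TRUE), 2)
#>            2h    6h   24h   48h   4d   7d  14d  21d  35d
#> hh_like -0.71 -0.89 -0.65 -0.78 0.61 0.52 0.68 0.49 0.73
```

The one injected coherent set is recovered at raw p `1/1001` (the floor at
`B = 1000`), adjusted p ≈ 0.02 across the 20 tested sets, while the 19
null sets stay non-significant; its scaled mean profile shows the
late-sustained shape (suppressed early, flat induction from day 4 on).

From the shell, the same pipeline runs on files:

```sh
Rscript inst/cli/bootgsa simulate --out-dir sim --seed 42
Rscript inst/cli/bootgsa run --expr sim/matrix.tsv --sets sim/sets.gmt \
    --out results.tsv --boot 1000 --seed 42 --profiles-out profiles.tsv
```

`results.tsv` holds one row per set (`set_name`, `set_size`, `overlap`,
`d`, `p_raw`, `p_adj`, `significant`, then the scaled set-mean profile per
time point), ordered by raw p-value; `profiles.tsv` is the heatmap-ready
profile matrix ordered early-to-late by peak time.

See `vignettes/dynamic-gene-sets.Rmd` for the model, the design choices
behind the defaults, and what the synthetic benchmark does and does not
emulate.

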