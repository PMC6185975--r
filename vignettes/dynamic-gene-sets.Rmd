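---
title: "Detecting dynamically expressed gene sets in an injury time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dynamically expressed gene sets in an injury time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootGSA)
```

## The question and the model

Regeneration studies commonly profile a tissue at a handful of time points
after injury — for example a microarray time course of the regenerating
newt heart sampled at 2 h through 35 days postinjury — and ask which
*pathways*, rather than which individual genes, change coherently over
time. bootGSA implements a self-contained set-level test of that question.

Given a genes × time-points matrix, each gene's profile is z-scaled across
the `M` time points, `(x - mean(x)) / sd(x)`, so genes measured at very
different absolute levels contribute equally to set averages. For a gene
set `S`, the test statistic is the Euclidean distance

    d = || mean profile of genes in S  -  background profile ||

where the background profile is the per-time-point mean over *all* scaled
genes. A set whose members move together over the time course pulls its
mean profile away from the background (which is close to flat, since every
scaled row sums to zero); incoherent sets average out towards it.

Significance is assessed by resampling: `B` random gene sets of the same
size are drawn from the full universe, each draw's distance to the fixed
background forms the null distribution `d0`, and the empirical p-value is
the plus-one-corrected strict exceedance fraction

    p = ( #{ d0_b > d } + 1 ) / ( B + 1 ).

Ties between a null distance and `d` do not count as exceedances, and the
correction keeps `p` in `[1/(B+1), 1]` — an empirical p-value is never
zero. P-values across the testable sets are then adjusted for multiple
testing and sets below the adjusted-p threshold are reported as
dynamically expressed.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `B` | 1000 | null resamples per set; the p-value floor is `1/(B+1)` |
| `alpha` | 0.05 | reporting threshold on the adjusted p-value |
| `adjust_method` | `"BH"` | Benjamini–Hochberg FDR; `holm`/`bonferroni` available |
| `sampling` | without replacement | a random "gene set" is a subset of the universe |
| `min_overlap` | 3 | members that must be present for a set to be testable |
| `sd_denominator` | `"sample"` (`M - 1`) | row-scaling divisor; `"population"` available |
| `seed` | — | single integer controlling the whole run |

Several of these are genuine design choices rather than forced readings,
and we state our reasoning:

* **Sampling without replacement.** A random gene set is naturally a
  *subset* of the universe — drawing the same gene twice into a "set" has
  no biological meaning — so the default null draws size-matched subsets.
  With-replacement sampling is exposed as an option and tested; at set
  sizes far below the universe size the two are nearly indistinguishable.
* **Null draws do not exclude the observed set's members.** The null is
  the distance distribution of an *arbitrary* same-sized set, and members
  of `S` are a negligible fraction of the universe.
* **Size-matching uses the overlap**, i.e. the number of members actually
  present in the matrix, not the nominal set size in the GMT file: the
  observed statistic averages only present genes, so the null must too.
* **Adjustment method.** "Adjusted p-value" is implemented as
  Benjamini–Hochberg FDR, the standard choice for screening many gene
  sets; Holm and Bonferroni are flags. Untestable sets contribute no
  hypothesis and are excluded from the multiplicity.
* **`min_overlap = 3`.** A "set" represented by one or two measured genes
  degenerates into a gene-level test; such sets are reported as not
  testable rather than tested badly. Every skip is logged.
* **Scaling denominator.** `sd` with divisor `M - 1`, matching R's `sd()`
  and the common convention in expression analysis; the population divisor
  is available and only rescales every row by the same constant, leaving
  p-values unchanged.
* **Unequal time spacing is ignored.** The grid (hours to weeks) is
  treated as ordered labels; the Euclidean statistic weights every time
  point equally. No time-warping or spline smoothing is attempted.

## Determinism and numerical choices

A run is fully determined by one integer seed. Each set's null uses a seed
derived from a stable string hash of `(seed, set name)`, so per-set nulls
are independent streams and adding or removing one set does not perturb
any other set's p-value. The RNG state of the calling session is restored
afterwards.

Missing values are never imputed: genes with any missing entry, and genes
with zero variance across time (which cannot be z-scaled), are filtered
out before scaling, with counts logged per reason. A matrix left empty by
filtering is an error, not a silent no-op. Ties in the results table are
broken lexicographically by set name, making output files byte-identical
across repeated runs.

`exact_p()` is a verification oracle, not an analysis path: it enumerates
all `choose(N, |S|)` subsets of a small universe and applies the same
plus-one-corrected exceedance formula. When comparing the sampled null to
this oracle one must note a discretization subtlety: the oracle's
correction shifts it by roughly `1/choose(N, |S|)`, so meaningful
agreement at Monte-Carlo precision requires universes with at least
a few hundred enumerable subsets. Our verification suite uses universes of
18–21 genes with sets of 3 (about 800–1300 subsets, well under the 10^5
enumeration cap), where that shift is an order of magnitude below the
3-standard-error comparison band at `B = 10^4`.

## What the synthetic generator emulates

`simulate_dataset()` produces a matrix, a GMT-compatible set collection
and ground-truth labels under

    x[g, t] = baseline[g] + scale[g] * ( effect[g] * template[g, t] + eps[g, t] )

with i.i.d. Gaussian noise. Two unit-norm, mean-centered phase templates
mimic the two-wave injury response seen in regeneration time courses: an
*early transient* shape (induced over the first third of the time points,
suppressed after — the inflammatory-response pattern) and a *late
sustained* shape (flat induction from the midpoint on — the pattern of a
signaling pathway that switches on and stays on). Members of a non-null
set share their template; non-null sets are disjoint so the truth labels
are unambiguous; null sets are independent random draws.

The per-gene `baseline` (sd 2) and multiplicative `scale` (uniform on
0.5–2) emulate probe-level magnitude differences and are absorbed by row
z-scaling; the effect enters *before* that transform, so detectability is
governed by the effect-to-noise ratio (`effect` is the template amplitude
in noise-sd units), not by raw units. Defaults are a 2,000-gene universe
on the nine-point grid `2h … 35d` with `noise_sd = 1`; the deposited-scale
18,560-gene matrix is the same code path with a larger `n_genes`.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: gene–gene correlation beyond set
membership, array batch structure, heavy-tailed or intensity-dependent
microarray noise, and overlap between real pathways. A calibrated type-I
error on independent Gaussian noise does not guarantee calibration under
strong inter-gene correlation, where the effective null spread is wider.

## Simulation study sizes

The packaged simulation studies use a 2,000-gene universe, sets of size
50, `B = 1000`, 20 replicate seeds for power/recovery checks and 500 null
sets for type-I calibration; the oracle comparison uses `B = 10^4` over 20
instances. One full-scale run (18,560 genes × 9 time points × 50 sets ×
`B = 1000`) is exercised as well and completes in a few seconds, so the
method is comfortably interactive at the size of the deposited dataset.

## Worked example

```{r example, eval = FALSE}
sets <- c(list(set_spec("hh_like", 50, "late_sustained", effect = 3)),
          lapply(1:19, function(i) set_spec(sprintf("null_%02d", i), 50, "null")))
ds <- simulate_dataset(synthetic_config(n_genes = 2000, sets = sets, seed = 42))
res <- run_analysis(ds$matrix, ds$sets, analysis_config(B = 1000, seed = 42))
res
profile_report(res, significant_only = TRUE)
```

## Known limitations

* The statistic is self-contained (set versus background); it does not
  implement competitive enrichment variants, gene-level permutation nulls
  or asymptotic approximations — an intentional scope boundary.
* Probe-to-gene mapping, cross-array normalization and batch correction
  are upstream concerns: the input matrix is assumed normalized as
  deposited.
* With `B = 1000` the smallest attainable raw p-value is `1/1001`; after
  FDR adjustment across many sets this floor can limit how many sets can
  clear a strict threshold. Increase `B` when screening large collections.
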