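# bcrclone

Tidy clonality analysis of B cell receptor (BCR) repertoires from bulk
RNA-seq, built for sorted innate-like B cell populations (B-1a, B-1b)
compared across genotypes (wild-type vs knockout). It consumes TRUST4
report tables or AIRR rearrangement TSVs and answers the questions such a
study asks: how many distinct CDR3 specificities does each mouse carry, how
much of each pooled repertoire is concentrated in *replicated* clones, is
clonal restriction associated with genotype, and which isotypes, V/D/J
segments and V–J pairings dominate?

## The statistics at the core

* **Clonotype** = the set of rearrangements sharing one CDR3 amino-acid
  sequence (`junction_aa`). Pooling all samples of a group, clone *i* has
  frequency *f<sub>i</sub>* = (pooled transcript count of *i*) / (pooled
  total). A clone is **replicated** when *f<sub>i</sub>* > 1% (strict); the
  **coverage** of the replicated set is Σ *f<sub>i</sub>* over replicated
  clones.
* **Exact Mann-Whitney rank-sum test** for per-sample statistics at n = 3–6
  per group: the null distribution of the rank sum W is enumerated by
  dynamic programming, and the two-sided p is 2 × min(P(W ≤ w), P(W ≥ w)),
  capped at 1. Complete separation of 4 vs 4 gives p = 2/C(8,4) = 0.02857;
  3 vs 4 gives 0.05714 — the smallest values those designs can produce.
  Ties or larger groups fall back to a flagged, tie-corrected normal
  approximation.
* **Pearson chi-squared** (no continuity correction) on the 2×2 table of
  replicated/non-replicated × genotype, in unique-clone and
  total-transcript modes.
* A **seeded V(D)J simulator** (toy germline segments, geometric trims,
  Poisson N-insertions, two-component clone sizes, multinomial sampling)
  generates AIRR-format studies with ground truth, so every stage is
  verified without external data.

## Worked example

```r
library(bcrclone)

sim <- simulate_study(seed = 1)          # 4+4 B-1a, 4+3 B-1b samples
res <- run_analysis(sim$data)
res
#> BCR repertoire analysis
#>   15872 records across 15 samples; threshold = 0.01
#>   Replicated-sequence summaries:
#>  chain_class subset genotype n_replicated n_unique replicated_coverage
#>        heavy   B-1a       WT            4      800              0.1448
#>        heavy   B-1a       KO           13      300              0.7252
#>        heavy   B-1b       WT            4      999              0.0959
#>        heavy   B-1b       KO           12      600              0.2473
#>        light   B-1a       WT            4      500              0.1530
#>        light   B-1a       KO           10      200              0.6576
#>        light   B-1b       WT            4      700              0.1002
#>        light   B-1b       KO           10      400              0.2150
```

The KO repertoires are visibly restricted: in B-1a heavy chains, 13
replicated clones cover 72.5% of all KO transcripts while the WT's 4 cover
14.5%, and the KO groups carry far fewer unique CDR3s. The association of
that partition with genotype:

```r
res$contingency$heavy$`B-1a`$unique
#>                 genotype
#> status            WT  KO
#>   replicated       4  13
#>   non_replicated 796 287
tidy(res$chi2$heavy$`B-1a`$unique)
#>   statistic    df    p_value
#> 1      21.1     1 0.00000443
```

An exact rank test on per-sample unique counts (here two samples tie, so
the flagged normal fallback is used):

```r
tidy(res$rank_tests$heavy$`B-1a`)
#>   statistic p_value method                  n1    n2 ties
#> 1        16  0.0202 normal-approximation     4     4 TRUE
```

Shared-repertoire overlap between the two KO subsets recovers the planted
public expansion:

```r
res$overlap[["B-1a KO vs B-1b KO"]]
#> CDR3 overlap across 2 sets: 13 shared sequence(s)
#>    label n_unique n_nonshared pct_nonshared
#>  B-1a KO      300         287         95.7%
#>  B-1b KO      600         587         97.8%
```

`write_analysis(res, "out/")` writes every table as TSV plus a single
`report.json`; `emulate_study("study/", seed = 1)` writes the simulated
study as per-sample AIRR TSVs with a manifest, ground truth and YAML
config; `read_study("study/manifest.tsv")` reads it (or any real study laid
out the same way) back. See `vignette("bcr-clonality")` for the model,
parameter and design details.

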