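---
title: "Clonality analysis of B cell receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality analysis of B cell receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrclone)
library(dplyr)
```

## The analysis

`bcrclone` analyses B cell receptor (BCR) repertoires reconstructed from
bulk RNA-seq of sorted B cell populations — for example TRUST4 report tables
or AIRR rearrangement TSVs from innate-like B-1a and B-1b cells of wild-type
(WT) and knockout (KO) mice. The unit of analysis is the *clonotype*: the
set of rearrangements sharing one CDR3 amino-acid sequence. Nucleotide
variants that translate identically are merged, because the biological
question — how many distinct antigen-binding specificities does a population
carry, and how unevenly are they expressed? — lives at the protein level.

The pipeline computes, per cell subset and chain class:

* **Per-sample unique CDR3 counts**, the diversity statistic compared
  between genotypes with an exact Mann-Whitney rank-sum test.
* **Pooled clone tables**: all samples of one genotype within one subset are
  pooled with abundance weighting; each clone's frequency is its share of
  the pooled transcript total. A clone is classified **replicated** when its
  pooled frequency strictly exceeds a threshold, 1% by default. The
  *coverage* of the replicated set (the summed frequency of replicated
  clones) summarises how much of the repertoire a handful of expanded
  specificities occupies.
* **Contingency tables** of replicated vs non-replicated against genotype,
  in unique-clone and total-transcript modes, tested with an uncorrected
  Pearson chi-squared statistic.
* **Isotype distributions** (IgM/IgD/IgG/IgA/IgE by constant-gene prefix,
  IgG subclasses collapsed), **V/D/J usage** at family or gene level,
  **V–J pairing matrices** (the table a circos plot encodes), and
  **kappa/lambda ratios**.
* **Multi-set CDR3 overlap** (a shared sequence is one expressed at least
  once in every set compared) and **top-clone tracking** of a reference
  group's most abundant CDR3s across all groups.

## The exact rank-sum test

Group sizes of three to six mice make asymptotic rank tests unreliable, so
the package enumerates the exact null distribution of the rank sum by
dynamic programming over achievable rank sums (the number of size-$n_1$
subsets of ranks $1..n_1+n_2$ attaining each sum). The two-sided p-value is
twice the smaller tail, with the observed value included in its tail and the
total capped at 1. This tail-doubling convention is what makes complete
separation of 4 vs 4 mice give $p = 2/\binom{8}{4} = 0.02857$ and 3 vs 4
give $p = 2/\binom{7}{3} = 0.05714$ — the minimum achievable levels for
those designs, which is worth remembering when interpreting "trending"
results from small cohorts.

Ties cannot occur in a valid exact enumeration over distinct ranks, so tied
data (and groups with both sizes above eight) fall back to mid-ranks with a
tie-corrected normal approximation, and the result is flagged
`normal-approximation`. No continuity correction is applied in either the
normal fallback or the chi-squared test; with the transcript-scale counts
that enter the contingency tables a correction is immaterial, and the
uncorrected Pearson statistic is the standard reading of "chi-squared test".
The test suite checks the exact path against brute-force enumeration of all
$\binom{n_1+n_2}{n_1}$ labelings and against `stats::wilcox.test`, and the
chi-squared against the closed 2×2 formula and
`stats::chisq.test(correct = FALSE)`.

## Choices the data format leaves open

Several details are not dictated by the rearrangement files themselves;
the package fixes defaults and exposes switches:

* **Abundance column** (AIRR input): `consensus_count`, then
  `duplicate_count`, then 1 — the AIRR standard allows either count.
  TRUST4 input uses the report's read count, not its `frequency` column, so
  pooling across samples stays in a common currency (reads).
* **Productive filtering**: analysis entry points keep only productive
  records whose CDR3 runs from the conserved cysteine to the conserved
  W/F anchor with no stop (`filter_productive()`, disable with
  `analysis_config(productive_only = FALSE)`). Translated-CDR3 statistics
  require translatable junctions; source data rarely state their filter.
* **Frequency denominator**: transcript abundance by default; a
  `weighting = "clonotype"` switch counts each record once instead.
* **Pooling for the threshold**: the replicated rule is applied to the
  pooled group frequency (matching pooled-sample reporting); a
  `pooling = "per_sample"` switch instead flags clones exceeding the
  threshold inside any single sample.
* **Threshold**: 0.01 with a strict `>`, so a clone at exactly 1% is *not*
  replicated ("greater than 1%" is an exclusive bound).
* **Chain classes**: heavy (IGH) and light (IGK and IGL combined) are
  analysed separately; light-chain lambda/kappa composition is reported by
  `kappa_lambda_ratio()`.
* **Clone-level V/J representative**: the modal (highest-abundance) call
  among a clone's records, ties broken alphabetically — multi-mapping
  across samples is resolved deterministically and logged nowhere else.
* **Per-segment comparisons** are reported without multiplicity adjustment,
  matching per-segment Wilcoxon reporting conventions; `adjust = TRUE`
  applies Benjamini–Hochberg.

## The synthetic repertoire generator

Real repertoire data cannot ship with a package, so every stage is
validated against a seeded V(D)J simulator with known ground truth
(`simulate_repertoire()`, `simulate_study()`, `emulate_study()`).

**Germline model.** A toy segment library is generated from the seed, not
copied from IMGT, to avoid any external reference: per locus at least 8 V,
4 D (heavy only) and 4 J segments whose junction-contributing parts are
short in-frame non-stop codon runs, V parts starting with the cysteine
codon and J parts ending with the tryptophan (heavy) or phenylalanine
(light) anchor. V families mirror the murine B-1 skew — IGHV11 heaviest,
then IGHV12 and IGHV1 — so family-level analysis is exercised, and light
clones split IGK/IGL 95:5 (B-1a) or 88:12 (B-1b).

**Junction model.** V–N1–D–N2–J for heavy chains, V–N–J for light:
geometric deletions (mean 1.5 nt per edge, anchors protected), Poisson
N-insertions (mean 4 nt per site) of uniform bases. With
`productive_only = TRUE`, non-productive junctions are resampled *holding
the drawn segments fixed* — only trims and insertions are redrawn. This
matters: resampling the segments too would condition usage on productivity
and measurably deplete stop-prone V segments, breaking the designed usage
frequencies; with fixed segments, realised usage matches the configured
weights up to multinomial error by construction.

**Clone sizes.** A deliberately simple two-component model: `expanded_count`
clones share `expanded_mass` of the frequency vector in equal parts, the
background shares the rest (uniform, gamma/Dirichlet-distributed with shape
`param`, or a rank power law). Background weights are constrained below the
expanded share, so the ground-truth "expanded" flag is exactly the set of
largest clones and the >1% classifier's truth is unambiguous. Recovery
tests that need every background clone bounded away from the threshold use
the uniform law, making the premise hold by construction rather than with
high probability.

**Study design.** `simulate_study()` reproduces the sorted-cell design of
4 WT + 4 KO B-1a and 4 WT + 3 KO B-1b samples, each sample carrying a
heavy-chain pool (3,000 reads) and a light-chain pool (2,000 reads). The
default effect configuration targets the replicated-coverage pattern the
analysis is designed to detect — roughly 72% (KO) vs 15% (WT) coverage in
B-1a and 25% in KO B-1b, with 13/12 expanded heavy clones in the KO groups —
while pool sizes (300–1,000 clones per group) are desk-scale rather than
the tens of thousands of clonotypes a real bulk RNA-seq repertoire can
yield. No quantitative clone-generation effect size is available to
calibrate against, so the defaults are chosen to reproduce the qualitative
ordering (KO: fewer unique CDR3s, more replicated mass) with complete
separation between genotypes. The two KO groups share their expanded clones
(public expansions across subsets), and the WT B-1a expanded clones are
planted into the KO B-1a background so top-clone tracking has a nonzero
cross-group signal. `effect = "null"` draws both genotypes from identical
parameters with no sharing, for type-I-error checks.

**Reproducibility.** All randomness flows from one master seed through
derived per-group and per-sample seeds (recorded in the manifest);
`emulate_study()` output is byte-identical for a fixed seed.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: somatic hypermutation and clonal lineages,
realistic IMGT germline sequences and allele diversity, selection and
affinity dynamics, sequencing error, library-preparation biases, and
chimeric or partial assemblies beyond simple partial-CDR3 markers. The
generator validates the *arithmetic* of the pipeline (classification,
conservation, test calibration), not the biology of any particular dataset.

## Numerical and degenerate-input conventions

* Clone frequencies are held as doubles; frequency sums are asserted to 1
  within 1e-9 after pooling, and pairing-matrix marginals match usage
  tables exactly (same floating-point path).
* A clone at exactly the threshold is non-replicated (strict inequality).
* Empty pools, zero marginals, group-key mismatches and missing metadata
  abort with typed conditions (`bcrclone_empty_error`,
  `bcrclone_degenerate_error`, ...) naming the offending sample or column.
* A sample with no lambda transcripts reports an infinite kappa/lambda
  ratio with a `degenerate` flag; rank tests operate on ranks, so infinite
  ratios remain usable unless a whole comparison is degenerate.
* Groups with fewer than two samples per genotype skip rank tests with a
  warning; pooled statistics are still emitted.
* Junction resampling has a bounded retry budget (500 rounds); exhausting
  it signals an inconsistent configuration rather than looping forever.

## Worked example

```{r study}
sim <- simulate_study(seed = 1)
res <- suppressMessages(run_analysis(sim$data))
res
```

```{r tests}
tidy(res$rank_tests$heavy$`B-1a`)
res$contingency$heavy$`B-1a`$unique
tidy(res$chi2$heavy$`B-1a`$unique)
```

```{r plots, fig.width = 6, fig.height = 4}
plot_unique_counts(bind_rows(res$unique_counts$heavy))
autoplot(res$clone_tables$heavy$`B-1a`$KO)
```

## Problem sizes used in validation

The shipped test-suite and verification runs use desk-scale simulations
chosen so the whole suite re-runs in minutes on one core: 200 seeds for
classifier-recovery checks (210 clones, 4 × 10,000 reads each), 300 seeds
for the null-calibration check of the 4-vs-3 rank test, 20 seeds for
sampling-distribution checks, and single-seed study simulations
(~15,000–16,000 records across 15 samples) for end-to-end pattern checks.
These sizes are the package's own validation choices; the same functions
run unchanged on full-scale repertoires.

## Known limitations

* The exact rank-sum path requires untied data; heavily tied per-sample
  statistics (e.g. many zero usage frequencies) silently use the flagged
  normal approximation, which is anti-conservative at n ≤ 5.
* Clone identity by CDR3 amino-acid string ignores convergent
  recombination; two independent rearrangements with one translated
  junction are one clone here.
* The chi-squared test treats pooled clones as independent observations, as
  the contingency-table construction implies; transcripts from one clone
  are correlated, so total-mode p-values are best read as descriptive.
* Overlap analysis is presence-based and therefore sensitive to sequencing
  depth; it makes no abundance-aware similarity claim (no Jaccard/Morisita
  indices).
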