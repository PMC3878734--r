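---
title: "Selecting stable reference genes from RNA-Seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes from RNA-Seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

qPCR expression measurements are normalized against reference
(housekeeping) genes assumed to be constant across the tissues, genotypes
and treatments under study. That assumption fails often enough — classic
references such as actin, ubiquitin or EF1-alpha drift with developmental
stage — that candidates must be validated per organism and experimental
system. When a multi-sample RNA-Seq data set for the system exists, it can
be mined directly: a good reference gene is one whose read counts are
abundant (so its signal is robust to sampling error) and stable (low
coefficient of variation, CV = SD/mean) across all samples, and which is
never called differentially expressed between any two conditions.

`refstab` implements that mining pipeline for a genes x samples count
matrix with a genotype/stage/treatment design, modelled on a grapevine
berry study with 47 samples from 14 genotypes over 4 phenological and
treatment conditions, plus the downstream qPCR validation arithmetic
(standard curves, Ct variability, geNorm stability ranking).

## Pipeline stages and their models

### 1. Non-differential-expression (NDE) filter

For every pair of condition labels, each gene is tested for a shift in
relative expression with an exact conditional binomial test: summing the
gene's counts within the two groups, the group-A sum given the two-group
total `n` is Binomial(n, p0) under the null, with p0 = group A's share of
the total size factors. Two-sided p-values sum all outcomes no more likely
than the one observed. Overdispersion relative to Poisson sampling is
handled with the negative-binomial variance function `var = mu + phi*mu^2`:
the binomial variance is inflated by `1 + phi*m` (m the mean
size-factor-scaled count per sample), and the p-value is then taken from a
t reference with `n_A + n_B - 2` degrees of freedom, which absorbs the
sampling noise of the estimated dispersion. `phi` is estimated per gene by
a moment estimator, pooling within-condition variances across all
conditions. P-values are Benjamini–Hochberg adjusted within each
comparison.

A gene is kept as NDE when it (a) has adjusted p >= alpha (default 0.05) in
every comparison, (b) carries at least 100 reads in every sample, and (c)
has CV at most `cv_cap` (default 0.65) — the variation-index criterion.
The cap matters: genes with high biological dispersion that are not
systematically shifted pass the DE test, and if left in they contaminate
the resampling null of the next stage, dragging both selection thresholds
upward until only high-mean noisy genes can clear them. The 0.65 default
reflects the upper CV bound observed in the study's accepted NDE set;
disable it with `cv_cap = NULL` to rely on the resampling thresholds alone.

Size factors default to median-of-ratios estimates and are refined
iteratively: after a first round of tests they are re-estimated using only
the genes currently classified as non-DE, and the tests rerun (two passes
by default). This is the control-gene-normalization idea: when a
substantial fraction of the transcriptome shifts between conditions,
factors computed from all genes absorb composition bias and would make
genuinely stable genes look differential.

The test is deliberately simple — a full reimplementation of edgeR's
empirical-Bayes machinery is out of scope — and `select_nde()` accepts
externally computed per-comparison p-values so a dedicated DE package's
output can drive the same filter.

### 2. Descriptive statistics

`gene_stats()` computes per-gene total, mean, variance, SD and CV across
samples (sample SD, n−1 denominator; a `sd_type` flag switches to the
population convention since spreadsheet-based analyses differ).
`describe_stats()` gives five-number summaries with linear-interpolation
quantiles (R type 7), `stat_correlations()` the Pearson relationships among
mean, variance and CV, and `rank_by_cv()` the CV-ascending ranking with
deterministic tie-breaking (descending mean, then gene id).

Under Poisson, quasi-Poisson or negative-binomial count models, variance
rises with the mean while the CV is approximately mean-free, which is why
mean and CV — not mean and variance — are the two screening axes.

### 3. Resampling thresholds

The core selection rule asks: is this gene's mean higher, and its CV lower,
than chance rearrangement of the observed counts would produce? A null is
built by pooled resampling: each of `n_pseudo` (default 10,000) pseudo
genes is a vector of `n_samples` counts drawn uniformly with replacement
from the pooled entries of the NDE matrix, and its mean and CV are computed
exactly as for real genes. Sampling with replacement is the standard
bootstrap reading of "sampled at random" and keeps pseudo genes i.i.d.

Thresholds are exact order statistics of the sorted pseudo values with
index `k = round(p * n_pseudo)` clamped to `[1, n_pseudo]` — at the default
10,000 pseudo genes the 97.5% mean threshold is the 9,750-th sorted mean
and the 2.5% CV threshold the 250-th sorted CV, exact products where any
rounding rule agrees. Genes with mean strictly above and CV strictly below
the thresholds are selected ("above"/"below" read literally); genes sitting
exactly on a threshold are reported separately rather than silently
classified. `threshold_sweep()` applies the whole percentile ladder —
(5, 95), (2.5, 97.5), (1, 99), (0.1, 99.9) by default — to one shared
pseudo-gene set, which guarantees the selections are nested and their sizes
weakly decreasing.

### 4. geNorm stability validation

Candidates are validated on qPCR-type data. Ct values are transformed to
relative quantities with the per-gene standard-curve rule
`quantity = (1+E)^(Ct_min − Ct)`, so each gene's lowest-Ct sample is its
calibrator. The geNorm statistic for gene j is
`M_j = mean over partners k of SD over samples of log2(q_j / q_k)`;
two ideal references track each other and have pairwise variation 0
regardless of per-sample loading. `stepwise_ranking()` removes the highest-M
gene each round (ties broken by gene id and logged) until two remain; those
two have identical M by construction and are reported as an unordered pair.
The optional `pairwise_variation()` gives geNorm's V(n/n+1) statistic for
choosing how many references to use. Sample SD is the default convention,
with a `sd_type` flag, since spreadsheet geNorm implementations vary.

### 5. qPCR support tools

`fit_standard_curve()` regresses Ct on log10 input quantity and converts
the slope to amplification efficiency `E = 10^(−1/slope) − 1` (perfect
doubling: slope −3.3219, E = 100%). `efficiency_check()` flags efficiencies
outside the 83–110% acceptance window. `ct_variability()` summarises raw Ct
spread per gene with the same quantile convention as `describe_stats()`.
`relative_expression()` reports group means ± SE scaled to the lowest group
mean (or to a designated reference gene — the published phrasing admits
both readings, so both are provided).

## The synthetic-data generator

No raw study data ships with the package; `simulate_counts()` generates
matrices with the statistical structure the analysis assumes so every stage
is testable. Counts are negative binomial with variance `mu + phi*mu^2`,
mean `base_mean * size_factor * condition_fold_change`, base means drawn
log-uniformly over 330–3,700 reads (the study's observed NDE mean range)
across 47 samples, 14 genotypes and 4 conditions by default. Per-sample
size factors are lognormal (sd 0.2), normalized to geometric mean 1 so
planted means stay interpretable; `libsize_sd = 0` turns depth variation
off, since it is unstated whether the original counts were
depth-normalized before CV computation.

Three classes are planted: `stable` genes (fold change 1 everywhere,
dispersion 0.05 — CV ≈ 0.23, clearly below the study's NDE range, as
befits true housekeeping behaviour), `de` genes (4-fold shifts in half the
conditions, the strong-effect regime the filter must catch), and `noisy`
genes (fold change 1, dispersion 0.6 — CV ≈ 0.8). The default mix is 20
stable / 60 DE / 120 noisy in a 200-gene panel: roughly a third of
expressed genes strongly stage-responsive and most of the remainder highly
variable without systematic shifts, which is what berry-development
transcriptomes look like once low-expression genes are excluded. Truth
labels are returned for recovery tests.

What the generator does not emulate: GC/length biases, batch effects
beyond global size factors, gene–gene correlation, and mean-dependent
dispersion trends. Passing tests therefore demonstrate that the machinery
recovers planted structure under the stated count model, not that any
particular biological data set will yield equally clean selections.

`simulate_ct()` inverts the standard-curve transform
(`Ct = ct_ref − log(q)/log(1+E) + noise`), so Ct generation followed by
`ct_to_quantity()` recovers quantities exactly at zero noise, up to each
gene's global scale.

## Numerical choices and edge cases

* Sample (n−1) SD throughout, with population-SD flags where conventions
  differ; linear-interpolation quantiles everywhere.
* Genes with mean 0 keep an `NA` CV and are retained by `gene_stats()` but
  dropped (with a warning) from rankings.
* The exact binomial enumeration is used when `phi = 0` and the two-group
  total is at most 5×10⁵; beyond that, and whenever `phi > 0`, the
  t-referenced inflated-variance approximation applies.
* Seeds: every stochastic operation takes a seed and derives fixed child
  seeds per stage, so identical configurations produce byte-identical
  reports (checksummed in the run manifest).
* Decimal output always uses `.`; reports are plain CSV/JSON.
* The number of pairwise comparisons is `choose(n_conditions, 2)`; the
  pipeline performs all of them and records the count in the result.

## Problem sizes

The bundled tests run the full pipeline on 200-gene × 47-sample panels
with 2,000–10,000 pseudo genes, 2,000-gene null calibrations, and
100-replicate Ct recovery simulations; a complete run of the suite takes a
few seconds.

## Known limitations

* The DE stand-in is a two-group exact test with quasi-likelihood
  inflation; it has no GLM design, no TMM normalization and no
  empirical-Bayes dispersion shrinkage. For production DE calls, plug an
  external DE table into `select_nde(external_p = ...)`.
* Resampling thresholds inherit the composition of the NDE matrix; if
  high-dispersion genes are allowed through (`cv_cap = NULL`) the
  thresholds drift upward and selection power drops.
* geNorm's M is a relative criterion: co-regulated unstable genes can
  protect each other. The V(n/n+1) statistic is provided but no automatic
  cutoff is enforced.
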