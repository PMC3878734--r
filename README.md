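# refstab

Selection and validation of stable reference (housekeeping) genes for qPCR
normalization, mined from a multi-condition RNA-Seq count matrix.

qPCR quantification stands or falls with its reference genes, and the
usual suspects (actin, ubiquitin, EF1-α) drift across tissues, genotypes
and developmental stages. When an RNA-Seq data set covering the
experimental system exists — here modelled on a grapevine berry study with
47 samples, 14 genotypes and 4 phenological/treatment conditions — good
candidates can be identified directly from the counts. `refstab` is aimed
at plant molecular biologists and transcriptomicists doing exactly that.

## Method

For a genes × samples count matrix with a sample design, the pipeline:

1. **NDE filter** — keeps genes never called differentially expressed in
   any pairwise condition comparison (exact conditional binomial test on
   group-summed counts with quasi-likelihood overdispersion inflation
   `1 + φm̄`, Benjamini–Hochberg adjusted per comparison), carrying ≥ 100
   reads in every sample, with CV below a variation-index cap.
2. **Statistics** — per gene, mean μ and coefficient of variation
   CV = SD/μ across all samples; candidates should combine high μ
   (abundance) with low CV (stability).
3. **Resampling thresholds** — simulates 10,000 pseudo genes, each built
   from `n_samples` counts drawn with replacement from the pooled observed
   matrix, and takes exact order statistics of their sorted means and CVs
   (at 10,000: the 9,750-th mean for the 97.5% threshold, the 250-th CV
   for 2.5%). Genes with μ above and CV below the thresholds are selected,
   over a ladder of percentile pairs yielding nested selections.
4. **geNorm validation** — transforms Ct values to relative quantities via
   `q = (1+E)^(Ct_min − Ct)` and ranks candidates by the stability measure
   `M_j = mean_k SD_s( log2 q_j / q_k )`, excluding the least stable gene
   per round until the most stable pair remains.
5. **qPCR tools** — standard-curve fits (`E = 10^(−1/slope) − 1`),
   efficiency range checks (83–110%), Ct variability summaries, relative
   expression profiles.

A negative-binomial simulator (`simulate_counts()`, `simulate_ct()`) with
planted stable / differential / noisy gene classes reproduces the study's
design so the whole pipeline is testable without any sequencing data.

## Worked example

```r
library(refstab)
sim <- simulate_counts(sim_config(seed = 1))   # 200 genes x 47 samples
cfg <- run_config(seed = 1)
man <- run_pipeline(sim$counts, cfg, ct = "simulate")
man
#> run_manifest (seed 1 )
#>   genes: 200 input -> 21 NDE -> 7 selected
#>   most stable pair: gene0005_stable + gene0007_stable
man$sweep$table
#>   cv_percentile mu_percentile cv_threshold mu_threshold n_selected
#> 1         0.050         0.950    0.5906519     2071.021          7
#> 2         0.025         0.975    0.5679393     2132.340          7
#> 3         0.010         0.990    0.5458661     2200.915          7
#> 4         0.001         0.999    0.4940068     2365.234          6
```

Of 200 simulated genes, 21 survive the NDE/min-reads/variation-index
funnel; the resampling thresholds keep 6–7 of them depending on stringency
(tightening the percentiles can only shrink the selection — the runs share
one pseudo-gene set); and geNorm stepwise exclusion on simulated Ct data
names a most-stable pair that indeed comes from the planted stable class.
Per-gene statistics are in `man$stats`, the CV ranking via
`rank_by_cv(man$stats)`, and with `out_dir=` every stage lands on disk as
CSV/JSON together with a checksummed manifest.

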