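Package: refstab
Title: Reference Gene Selection from RNA-Seq Counts by Resampling
    Thresholds and geNorm Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers stable reference (housekeeping) genes for qPCR
    normalization from a genes-by-samples RNA-Seq count matrix. Implements
    a non-differential-expression filter across all pairwise condition
    comparisons, per-gene mean and coefficient-of-variation statistics, a
    pooled-resampling pseudo-gene simulation with order-statistic
    percentile thresholds on mean and CV, geNorm M-value stability ranking
    with stepwise exclusion on qPCR-derived relative quantities, and qPCR
    support tools (standard-curve amplification efficiency, Ct variability
    summaries, relative expression). A negative-binomial synthetic-data
    generator emulates the multi-genotype, multi-stage study design so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
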