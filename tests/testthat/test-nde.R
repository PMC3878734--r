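test_that("moment dispersion estimator matches direct arithmetic", {
  expect_equal(estimate_dispersion(c(50, 50, 50)), 0)
  # scaled mean 100, sample variance 600 -> (600 - 100) / 100^2 = 0.05
  y <- vector_with_moments(20, 100, sqrt(600))
  expect_equal(estimate_dispersion(y), 0.05, tolerance = 1e-12)
  # Poisson-like (var = mean) genes get phi = 0
  y2 <- vector_with_moments(20, 100, 10)
  expect_equal(estimate_dispersion(y2), 0)
  expect_warning(estimate_dispersion(c(0L, 0L, 0L)), "all-zero")
})

test_that("exact test equals the enumerated two-sided binomial", {
  # one gene: 100 total counts in group A vs 1,000 in group B, equal depths
  m <- rbind(g1 = c(40L, 60L, 480L, 520L),
             g2 = c(250L, 250L, 250L, 250L))
  colnames(m) <- paste0("s", 1:4)
  d <- data.frame(sample_id = colnames(m), genotype = "G",
                  stage = rep(c("A", "B"), each = 2), treatment = "none")
  cm <- count_matrix(m, d)
  de <- pairwise_de_test(cm, c("s1", "s2"), c("s3", "s4"),
                         size_factors = rep(1, 4), dispersion = 0)
  oracle <- stats::binom.test(100, 1100, 0.5)$p.value
  expect_equal(de$p_value[de$gene_id == "g1"], oracle, tolerance = 1e-12)
  # identical counts in both groups -> p ~ 1
  expect_gte(de$p_value[de$gene_id == "g2"], 0.99)
  expect_true(all(de$adjusted_p >= de$p_value))
})

test_that("group preconditions are enforced", {
  cm <- tiny_counts()
  expect_error(pairwise_de_test(cm, "s1", "s1"), "disjoint")
  expect_error(pairwise_de_test(cm, character(0), "s2"), "non-empty")
  expect_error(pairwise_de_test(cm, "s1", "s2",
                                size_factors = c(0, 1, 1)),
               "zero total size factor|positive")
})

test_that("min-reads rule excludes genes dipping below the floor", {
  m <- rbind(low = c(99L, 500L, 500L, 500L),
             hi  = c(500L, 500L, 500L, 500L))
  colnames(m) <- paste0("s", 1:4)
  d <- data.frame(sample_id = colnames(m), genotype = "G",
                  stage = rep(c("A", "B"), each = 2), treatment = "none")
  cm <- count_matrix(m, d)
  nde <- select_nde(cm, run_config(min_reads_per_sample = 100),
                    dispersion = 0.05, sf_iterations = 0)
  expect_false("low" %in% nde$gene_ids)
})

test_that("a perfect null keeps every gene above the read floor", {
  m <- matrix(rep(c(150L, 900L, 250L), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  d <- data.frame(sample_id = colnames(m), genotype = "G",
                  stage = rep(c("A", "B", "C"), each = 2), treatment = "none")
  nde <- select_nde(count_matrix(m, d), run_config(), dispersion = 0)
  expect_setequal(nde$gene_ids, c("g1", "g2", "g3"))
  expect_identical(nde$n_comparisons, 3L)   # all pairs of 3 conditions
  expect_error(select_nde(tiny_counts(stages = rep("x", 3))),
               "at least 2 conditions")
})

test_that("strong DE everywhere empties the NDE set", {
  cfg <- sim_config(n_stable = 0, n_de = 60, n_noisy = 0, de_log2fc = 4,
                    libsize_sd = 0, seed = 5)
  sim <- simulate_counts(cfg)
  nde <- select_nde(sim$counts, run_config(seed = 5))
  expect_length(nde$gene_ids, 0)
})

test_that("NDE selection is monotone in the read floor and in alpha", {
  sim <- simulate_counts(sim_config(seed = 6))
  # fixed size factors so the three runs differ only in the rule parameter
  base <- select_nde(sim$counts, run_config(seed = 6), sf_iterations = 0)
  stricter_reads <- select_nde(sim$counts,
                               run_config(min_reads_per_sample = 400, seed = 6),
                               sf_iterations = 0)
  looser_alpha <- select_nde(sim$counts, run_config(alpha = 0.01, seed = 6),
                             sf_iterations = 0)
  expect_true(all(stricter_reads$gene_ids %in% base$gene_ids))
  # smaller alpha flags less, so the kept set can only grow
  expect_true(all(base$gene_ids %in% looser_alpha$gene_ids))
})

test_that("planted-class recovery: stable kept, strong DE excluded", {
  kept_stable <- 0; n_stable <- 0; kept_de <- 0; n_de <- 0
  for (s in 1:3) {
    sim <- simulate_counts(sim_config(seed = s))
    nde <- select_nde(sim$counts, run_config(seed = s))
    st <- sim$truth$gene_id[sim$truth$class == "stable"]
    de <- sim$truth$gene_id[sim$truth$class == "de"]
    kept_stable <- kept_stable + sum(st %in% nde$gene_ids)
    n_stable <- n_stable + length(st)
    kept_de <- kept_de + sum(de %in% nde$gene_ids)
    n_de <- n_de + length(de)
  }
  expect_gt(kept_stable / n_stable, 0.9)
  expect_gt(1 - kept_de / n_de, 0.9)
})

test_that("externally supplied p-values drive the filter when given", {
  cm <- tiny_counts(stages = c("A", "A", "B"))
  ext <- data.frame(gene_id = c("g1", "g2"), comparison = "A vs B",
                    p_value = c(0.001, 0.9))
  nde <- select_nde(cm, run_config(min_reads_per_sample = 0), external_p = ext)
  expect_identical(nde$gene_ids, "g2")
})
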