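test_that("a constant pool gives degenerate pseudo genes", {
  m <- matrix(500L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ps <- simulate_pseudo_genes(m, n_pseudo = 50, seed = 1)
  expect_true(all(ps$mean == 500))
  expect_true(all(ps$cv == 0))
  expect_error(simulate_pseudo_genes(m, n_pseudo = 0), "n_pseudo")
})

test_that("pseudo-gene resampling is reproducible and unbiased for the pooled mean", {
  sim <- simulate_counts(sim_config(seed = 11))
  ps1 <- simulate_pseudo_genes(sim$counts, n_pseudo = 10000, seed = 11)
  ps2 <- simulate_pseudo_genes(sim$counts, n_pseudo = 10000, seed = 11)
  expect_identical(ps1$mean, ps2$mean)
  expect_identical(ps1$cv, ps2$cv)
  expect_identical(nrow(ps1), 10000L)
  pool <- as.numeric(sim$counts$counts)
  se <- sd(pool) / sqrt(47 * 10000)
  expect_lt(abs(mean(ps1$mean) - mean(pool)), 3 * se)
})

test_that("order-statistic indices and thresholds match a full-sort oracle", {
  expect_identical(order_stat_index(0.975, 10000), 9750L)
  expect_identical(order_stat_index(0.025, 10000), 250L)
  expect_identical(order_stat_index(0.25, 8), 2L)
  expect_identical(order_stat_index(0.0001, 100), 1L)  # clamped to 1
  set.seed(12)
  ps <- data.frame(mean = runif(777, 100, 2000), cv = runif(777, 0.1, 1))
  thr <- percentile_thresholds(ps, 0.025, 0.975)
  expect_identical(thr$cv_threshold, sort(ps$cv)[round(0.025 * 777)])
  expect_identical(thr$mu_threshold, sort(ps$mean)[round(0.975 * 777)])
  # sorted 1..8 at percentile 0.25 -> 2nd value
  ps8 <- data.frame(mean = sample(1:8), cv = sample(1:8) / 10)
  expect_equal(percentile_thresholds(ps8, 0.25, 0.75)$cv_threshold, 0.2)
})

test_that("thresholds are monotone in their percentiles", {
  set.seed(13)
  ps <- data.frame(mean = rgamma(5000, 4, 0.01), cv = rbeta(5000, 4, 4))
  mus <- vapply(c(0.9, 0.95, 0.99, 0.999),
                function(p) percentile_thresholds(ps, 0.01, p)$mu_threshold,
                numeric(1))
  cvs <- vapply(c(0.001, 0.01, 0.05, 0.1),
                function(p) percentile_thresholds(ps, p, 0.999)$cv_threshold,
                numeric(1))
  expect_true(all(diff(mus) >= 0))
  expect_true(all(diff(cvs) >= 0))
})

test_that("candidate selection applies strict above/below rules", {
  gs <- data.frame(gene_id = c("hi", "lo"), total = 0,
                   mean = c(1300, 1100), var = 0, sd = 0, cv = c(0.40, 0.40))
  class(gs) <- c("gene_stats", "data.frame")
  thr <- list(cv_threshold = 0.513, mu_threshold = 1208.2)
  res <- select_candidates(gs, thr)
  expect_identical(res$selected, "hi")
  expect_identical(res$n_selected, 1L)
  # vacuous threshold directions
  all_in <- select_candidates(gs, list(cv_threshold = Inf, mu_threshold = 0))
  expect_identical(all_in$n_selected, 2L)
  none <- select_candidates(gs, list(cv_threshold = Inf, mu_threshold = 1e9))
  expect_identical(none$n_selected, 0L)
  # boundary genes are flagged, not silently classified
  border <- select_candidates(gs, list(cv_threshold = 0.40,
                                       mu_threshold = 1000))
  expect_setequal(border$boundary, c("hi", "lo"))
  expect_identical(border$n_selected, 0L)
})

test_that("threshold sweep is nested, weakly decreasing and deterministic", {
  sim <- simulate_counts(sim_config(seed = 14))
  cfg <- run_config(n_pseudo = 5000, seed = 14)
  sw1 <- threshold_sweep(sim$counts, cfg = cfg)
  sw2 <- threshold_sweep(sim$counts, cfg = cfg)
  expect_identical(sw1$table$n_selected, sw2$table$n_selected)
  expect_true(all(diff(sw1$table$n_selected) <= 0))
  sels <- lapply(sw1$results, `[[`, "selected")
  for (i in seq_len(length(sels) - 1)) {
    expect_true(all(sels[[i + 1]] %in% sels[[i]]))
  }
})

test_that("an all-constant matrix selects nothing at any stringency", {
  m <- matrix(800L, 10, 6, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  gs <- suppressWarnings(gene_stats(m))
  sw <- threshold_sweep(m, gs, run_config(n_pseudo = 1000, seed = 15))
  expect_true(all(sw$table$n_selected == 0))  # no mean strictly above the pool
})

test_that("stable genes are selected preferentially over noisy genes with the same mean distribution", {
  # both classes draw base means from the same range, so selection rates are
  # directly comparable: the CV threshold should favour the stable class
  cfg <- sim_config(n_stable = 40, n_de = 0, n_noisy = 40, n_samples = 47,
                    libsize_sd = 0, seed = 16)
  sim <- simulate_counts(cfg)
  sw <- threshold_sweep(sim$counts, cfg = run_config(n_pseudo = 5000, seed = 16))
  sel <- sw$results[[1]]$selected
  st <- sim$truth$gene_id[sim$truth$class == "stable"]
  no <- sim$truth$gene_id[sim$truth$class == "noisy"]
  expect_gt(mean(st %in% sel), mean(no %in% sel))
})
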