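test_that("gene statistics match hand arithmetic and published-style rows", {
  m <- rbind(gA = c(1, 2, 3), gB = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  gs <- gene_stats(m)
  expect_equal(gs$mean, c(2, 5))
  expect_equal(gs$sd, c(1, 0))
  expect_equal(gs$cv, c(0.5, 0))
  # a 47-sample gene totalling 80,103 reads has mean 1704.3 (prints 1704)
  v <- vector_with_moments(47, 80103 / 47, 791)
  gs47 <- gene_stats(matrix(v, 1, 47, dimnames = list("g", paste0("s", 1:47))))
  expect_equal(gs47$total, 80103)
  expect_equal(round(gs47$mean), 1704)
  # mean * n_samples = total, exactly
  expect_equal(gs47$mean * 47, gs47$total)
})

test_that("population SD option uses the n denominator", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", paste0("s", 1:3)))
  expect_equal(gene_stats(m, sd_type = "population")$sd,
               sqrt(2 / 3), tolerance = 1e-12)
})

test_that("zero-mean genes keep a flagged undefined CV", {
  m <- rbind(g0 = c(0, 0, 0), g1 = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(gs <- gene_stats(m), "mean 0")
  expect_true(is.na(gs$cv[1]))
  expect_identical(nrow(gs), 2L)
})

test_that("CV is invariant under positive rescaling of a gene", {
  set.seed(8)
  v <- rpois(47, 800)
  m <- rbind(g = v, g10 = 10 * v)
  colnames(m) <- paste0("s", 1:47)
  gs <- gene_stats(m)
  expect_equal(gs$cv[1], gs$cv[2], tolerance = 1e-12)
})

test_that("five-number summaries use linear-interpolation quantiles", {
  m <- matrix(c(1:5, 11:15, 21:25), 3, 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  gs <- gene_stats(m)
  sm <- describe_stats(gs)
  mu <- sm[sm$stat == "mean", ]
  expect_equal(unlist(mu[c("min", "q1", "median", "q3", "max")]),
               c(min = 3, q1 = 8, median = 13, q3 = 18, max = 23))
  # even-length linear interpolation: median of means (3,3,13,23) is 8
  sm4 <- describe_stats(gs[c(1, 1, 2, 3), ])
  expect_equal(sm4$median[sm4$stat == "mean"], (3 + 13) / 2)
  one <- describe_stats(gs[2, , drop = FALSE])
  expect_true(all(one[one$stat == "mean", -1] == 13))
  expect_error(describe_stats(gs[0, ]), "empty")
})

test_that("Pearson correlations match direct covariance arithmetic", {
  set.seed(9)
  m <- matrix(rpois(5 * 6, 100), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  gs <- gene_stats(m)
  tab <- stat_correlations(gs)
  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  r_mv <- tab$r[tab$stat_a == "mean" & tab$stat_b == "var"]
  expect_equal(r_mv, direct(gs$mean, gs$var), tolerance = 1e-12)
  # self- and anti-correlation sanity through the same formula
  expect_equal(direct(gs$mean, gs$mean), 1, tolerance = 1e-12)
  expect_equal(direct(gs$mean, -gs$mean), -1, tolerance = 1e-12)
  # p-value follows the t transform of r
  n <- nrow(gs)
  tt <- r_mv * sqrt(n - 2) / sqrt(1 - r_mv^2)
  expect_equal(tab$p[tab$stat_a == "mean" & tab$stat_b == "var"],
               2 * pt(abs(tt), n - 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(stat_correlations(gs[1:2, ]), "at least 3")
})

test_that("NB simulations reproduce the mean-variance-CV correlation pattern", {
  cfg <- sim_config(n_stable = 500, n_de = 0, n_noisy = 0, n_samples = 47,
                    dispersion_stable = 0.25, libsize_sd = 0, seed = 10)
  gs <- gene_stats(simulate_counts(cfg)$counts)
  tab <- stat_correlations(gs)
  expect_gt(tab$r[tab$stat_a == "mean" & tab$stat_b == "var"], 0.9)
  expect_lt(abs(tab$r[tab$stat_a == "mean" & tab$stat_b == "cv"]), 0.1)
})

test_that("CV ranking sorts ascending with mean then id as tie-breaks", {
  gs <- data.frame(gene_id = c("g1", "g2", "g3"),
                   total = c(30, 30, 30), mean = c(10, 10, 10),
                   var = 0, sd = 0, cv = c(0.5, 0.3, 0.4))
  class(gs) <- c("gene_stats", "data.frame")
  expect_identical(rank_by_cv(gs)$gene_id, c("g2", "g3", "g1"))
  # tie on cv 0.49: the higher-mean gene (3,461) ranks first
  tie <- data.frame(gene_id = c("a", "b"), total = 0,
                    mean = c(1925, 3461), var = 0, sd = 0, cv = c(0.49, 0.49))
  class(tie) <- c("gene_stats", "data.frame")
  expect_identical(rank_by_cv(tie)$gene_id, c("b", "a"))
  gs$cv[2] <- NA
  expect_warning(rk <- rank_by_cv(gs), "undefined cv")
  expect_identical(nrow(rk), 2L)
})
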