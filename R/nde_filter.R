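#' Moment estimator of negative-binomial dispersion
#'
#' Estimates phi in the variance function `var = mu + phi * mu^2` from
#' size-factor-scaled counts: `phi = max(0, (s2 - m) / m^2)` with `m` the
#' scaled mean and `s2` the scaled sample variance. Poisson-like genes
#' (variance <= mean) get phi = 0.
#'
#' @param y integer counts for one gene.
#' @param size_factors positive per-sample scaling factors (default all 1).
#' @return dispersion estimate >= 0.
#' @examples
#' estimate_dispersion(c(50, 50, 50))            # no variance -> 0
#' @export
estimate_dispersion <- function(y, size_factors = rep(1, length(y))) {
  if (length(y) < 2L) stop("need at least 2 observations")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (all(y == 0)) {
    warning("all-zero gene: dispersion set to 0")
    return(0)
  }
  z <- y / size_factors
  m <- mean(z)
  s2 <- stats::var(z)
  max(0, (s2 - m) / m^2)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors estimated as the median, over genes,
#' of the ratio of each count to its gene's geometric mean across samples,
#' normalized to mean 1. Robust to composition bias: unlike raw column
#' totals it is not dragged by a block of strongly differential genes.
#' Falls back to normalized column totals when fewer than 10 genes have
#' all-positive counts.
#'
#' @param x a [count_matrix()] or numeric matrix.
#' @return positive numeric vector, one factor per sample, mean 1.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  pos <- rowSums(m <= 0) == 0L
  if (sum(pos) >= 10L) {
    lg <- log(m[pos, , drop = FALSE])
    ratios <- exp(lg - rowMeans(lg))
    sf <- apply(ratios, 2L, stats::median)
  } else {
    sf <- colSums(m)
  }
  sf / mean(sf)
}

# two-sided exact binomial p by the minimum-likelihood rule: sum the
# probabilities of all outcomes no more likely than the observed one
exact_binom_p2 <- function(x, n, p0) {
  d_obs <- stats::dbinom(x, n, p0)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Pairwise differential-expression test between two condition groups
#'
#' A simple exact test for count data: for each gene the counts are summed
#' within each group and, conditional on the two-group total `n`, the group-A
#' sum is Binomial(n, p0) under the null of equal relative expression, with
#' `p0` = group A's share of the total size factors. The two-sided p-value
#' sums all outcomes no more likely than the observed one. Overdispersion is
#' accommodated through a quasi-likelihood variance inflation `1 + phi * m`
#' (m = mean scaled count per sample): when `phi > 0` the p-value comes from
#' a normal approximation with the inflated variance. P-values are
#' Benjamini-Hochberg adjusted across genes within the comparison.
#'
#' @param x a [count_matrix()].
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param size_factors per-sample positive factors; default
#'   median-of-ratios factors from [size_factors()].
#' @param dispersion `NULL` to estimate per gene from within-group scaled
#'   counts (pooled), or a scalar/per-gene numeric to fix it (0 = pure
#'   Poisson sampling, exact test).
#' @param comparison label stored in the result (default built from the
#'   groups).
#' @return data.frame with columns `gene_id`, `comparison`, `p_value`,
#'   `adjusted_p`.
#' @export
pairwise_de_test <- function(x, group_a, group_b, size_factors = NULL,
                             dispersion = NULL, comparison = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ids <- colnames(x$counts)
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!all(c(group_a, group_b) %in% ids))
    stop("unknown sample ids in groups")
  if (is.null(size_factors)) size_factors <- refstab::size_factors(x)
  names(size_factors) <- ids
  sf_a <- size_factors[group_a]; sf_b <- size_factors[group_b]
  if (sum(sf_a) <= 0 || sum(sf_b) <= 0)
    stop("a group has zero total size factor")
  p0 <- sum(sf_a) / (sum(sf_a) + sum(sf_b))
  if (is.null(comparison))
    comparison <- paste0(group_a[1L], "...", group_b[1L])

  ca <- x$counts[, group_a, drop = FALSE]
  cb <- x$counts[, group_b, drop = FALSE]
  ya <- rowSums(ca); yb <- rowSums(cb)
  n_genes <- nrow(x$counts)

  if (is.null(dispersion)) {
    phi <- vapply(seq_len(n_genes), function(i) {
      za <- ca[i, ] / sf_a; zb <- cb[i, ] / sf_b
      # pool within-group moments so true DE does not inflate phi
      m <- mean(c(za, zb))
      s2 <- (sum((za - mean(za))^2) + sum((zb - mean(zb))^2)) /
        (length(za) + length(zb) - 2)
      if (m <= 0) 0 else max(0, (s2 - m) / m^2)
    }, numeric(1L))
  } else {
    phi <- rep_len(dispersion, n_genes)
  }

  df <- length(group_a) + length(group_b) - 2L
  p <- vapply(seq_len(n_genes), function(i) {
    n <- ya[i] + yb[i]
    if (n == 0) return(1)
    if (phi[i] <= 0 && n <= 5e5) return(exact_binom_p2(ya[i], n, p0))
    mbar <- mean(c(ca[i, ] / sf_a, cb[i, ] / sf_b))
    v <- n * p0 * (1 - p0) * (1 + phi[i] * mbar)
    # t reference absorbs the sampling noise of the estimated dispersion
    2 * stats::pt(-abs(ya[i] - n * p0) / sqrt(v), df = df)
  }, numeric(1L))

  data.frame(gene_id = rownames(x$counts), comparison = comparison,
             p_value = p, adjusted_p = pmin(1, stats::p.adjust(p, "BH")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select non-differentially expressed (NDE) genes
#'
#' Runs the pairwise DE test between every pair of distinct condition labels
#' and keeps genes that (a) are never called differentially expressed
#' (adjusted p >= alpha in EVERY comparison), (b) have at least
#' `min_reads_per_sample` reads in every sample, and (c) optionally stay
#' below a CV ceiling (`cv_cap`, disabled by default since the downstream
#' resampling stage thresholds CV itself).
#'
#' @param x a [count_matrix()] whose design yields >= 2 conditions.
#' @param cfg a [run_config()] supplying `alpha`, `min_reads_per_sample`
#'   and `cv_cap`.
#' @param external_p optional externally computed DE results (data.frame
#'   with `gene_id`, `comparison`, `p_value`), e.g. from a dedicated DE
#'   package; adjusted within each comparison and used instead of the
#'   built-in test.
#' @param dispersion passed to [pairwise_de_test()] when the built-in test
#'   runs.
#' @return object of class `nde_result`: list with `gene_ids` (character,
#'   in input order), `n_comparisons`, `de_table` (all per-gene
#'   per-comparison p-values) and the filter settings used.
#' @details When `dispersion` is `NULL`, a single per-gene dispersion is
#'   estimated once from the within-condition variances pooled across ALL
#'   conditions (not just the two being compared), which uses every
#'   residual degree of freedom available and keeps the comparisons
#'   consistent with each other.
#'
#'   Size factors are refined iteratively (`sf_iterations` extra passes):
#'   after an initial round of tests, the median-of-ratios factors are
#'   re-estimated on the genes currently classified as non-DE and the tests
#'   are rerun. When many genes are strongly differential, factors computed
#'   from the whole matrix absorb composition bias and would make genuinely
#'   stable genes look shifted; restricting the estimator to the apparent
#'   null set removes that bias, exactly as normalizing on control genes
#'   does.
#' @param sf_iterations number of size-factor refinement passes (0 disables
#'   refinement).
#' @export
select_nde <- function(x, cfg = run_config(), external_p = NULL,
                       dispersion = NULL, sf_iterations = 2L) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- sample_conditions(x)
  levs <- unique(cond)
  if (length(levs) < 2L)
    stop("NDE filtering needs at least 2 conditions in the design")
  pairs <- utils::combn(levs, 2L)

  if (is.null(external_p)) {
    sf <- size_factors(x)
    fixed_phi <- dispersion
    for (iter in 0:sf_iterations) {
      if (iter > 0L) {
        never <- tapply(de$adjusted_p >= cfg$alpha, de$gene_id, all)
        null_ids <- names(never)[never]
        if (length(null_ids) < 10L) break
        sf_new <- size_factors(x$counts[null_ids, , drop = FALSE])
        if (max(abs(sf_new - sf)) < 1e-8) break
        sf <- sf_new
      }
      phi <- if (is.null(fixed_phi)) pooled_dispersion(x$counts, sf, cond)
             else fixed_phi
      de <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- colnames(x$counts)[cond == pairs[1L, j]]
        b <- colnames(x$counts)[cond == pairs[2L, j]]
        pairwise_de_test(x, a, b, size_factors = sf, dispersion = phi,
                         comparison = paste(pairs[1L, j], pairs[2L, j],
                                            sep = " vs "))
      }))
    }
  } else {
    stopifnot(all(c("gene_id", "comparison", "p_value") %in% names(external_p)))
    de <- do.call(rbind, lapply(split(external_p, external_p$comparison),
      function(d) {
        d$adjusted_p <- pmin(1, stats::p.adjust(d$p_value, "BH"))
        d
      }))
    rownames(de) <- NULL
  }

  never_de <- tapply(de$adjusted_p >= cfg$alpha, de$gene_id, all)
  nde_ids <- names(never_de)[never_de]
  enough <- rownames(x$counts)[
    apply(x$counts >= cfg$min_reads_per_sample, 1L, all)]
  keep <- intersect(rownames(x$counts), intersect(nde_ids, enough))
  if (!is.null(cfg$cv_cap)) {
    gs <- gene_stats(x)
    low_cv <- gs$gene_id[!is.na(gs$cv) & gs$cv <= cfg$cv_cap]
    keep <- intersect(keep, low_cv)
  }
  structure(list(gene_ids = keep,
                 n_comparisons = ncol(pairs),
                 de_table = de,
                 alpha = cfg$alpha,
                 min_reads_per_sample = cfg$min_reads_per_sample,
                 cv_cap = cfg$cv_cap),
            class = "nde_result")
}

# per-gene NB dispersion from within-condition moments pooled over all
# condition groups of size >= 2
pooled_dispersion <- function(counts, sf, cond) {
  z <- sweep(counts, 2L, sf, "/")
  groups <- split(seq_along(cond), cond)
  groups <- groups[vapply(groups, length, integer(1L)) >= 2L]
  ss <- matrix(0, nrow(counts), length(groups))
  dfs <- numeric(length(groups))
  for (j in seq_along(groups)) {
    zi <- z[, groups[[j]], drop = FALSE]
    ss[, j] <- rowSums((zi - rowMeans(zi))^2)
    dfs[j] <- length(groups[[j]]) - 1L
  }
  s2 <- rowSums(ss) / sum(dfs)
  m <- rowMeans(z)
  ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
}

#' @export
print.nde_result <- function(x, ...) {
  cat(sprintf("nde_result: %d gene(s) kept over %d pairwise comparison(s)\n",
              length(x$gene_ids), x$n_comparisons))
  cat(sprintf("  alpha = %g, min reads/sample = %d\n",
              x$alpha, x$min_reads_per_sample))
  invisible(x)
}
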