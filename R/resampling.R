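#' Simulate pseudo-NDE genes by pooled resampling
#'
#' Builds the null distribution of per-gene mean and CV: each pseudo gene is
#' a vector of `n_samples` counts drawn uniformly with replacement from the
#' pooled set of all entries of the observed matrix, and its mean and CV are
#' computed exactly as for real genes. A real gene whose mean exceeds (and
#' whose CV falls below) the extremes of this null is stable and abundant
#' beyond what resampling noise alone produces.
#'
#' @param x a [count_matrix()] or numeric matrix.
#' @param n_pseudo number of pseudo genes (default 10,000).
#' @param seed integer seed.
#' @return data.frame of class `pseudo_gene_set` with columns `mean` and
#'   `cv`, one row per pseudo gene; attributes `n_samples`, `source_dim`
#'   and `seed`.
#' @export
simulate_pseudo_genes <- function(x, n_pseudo = 10000L, seed = 1L) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (!length(m)) stop("empty count matrix")
  if (n_pseudo < 1L) stop("n_pseudo must be >= 1")
  n_samples <- ncol(m)
  pool <- as.vector(m)
  set.seed(child_seed(seed, "pool"))
  draws <- matrix(pool[sample.int(length(pool), n_pseudo * n_samples,
                                  replace = TRUE)],
                  nrow = n_pseudo, ncol = n_samples)
  mu <- rowMeans(draws)
  s <- apply(draws, 1L, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  out <- data.frame(mean = mu, cv = cv)
  attr(out, "n_samples") <- n_samples
  attr(out, "source_dim") <- dim(m)
  attr(out, "seed") <- seed
  class(out) <- c("pseudo_gene_set", "data.frame")
  out
}

#' Order-statistic index for a percentile
#'
#' The k-th smallest of n sorted values represents the p-th percentile, with
#' `k = round(p * n)` clamped to `[1, n]`. At n = 10,000 this gives the
#' 9,750-th value for the 97.5% percentile and the 250-th for 2.5%.
#'
#' @param p percentile in (0, 1).
#' @param n number of values.
#' @return integer index k.
#' @export
order_stat_index <- function(p, n) {
  stopifnot(p > 0, p < 1, n >= 1)
  min(max(1L, as.integer(round(p * n))), as.integer(n))
}

#' Percentile thresholds from the pseudo-gene null
#'
#' Sorts the pseudo-gene means and CVs from lowest to highest and takes
#' exact order statistics: the `mu_percentile` point of the means (an upper
#' threshold real genes must exceed) and the `cv_percentile` point of the
#' CVs (a lower threshold real genes must stay under).
#'
#' @param pseudo a [simulate_pseudo_genes()] result.
#' @param cv_percentile,mu_percentile percentiles in (0, 1) with
#'   `cv_percentile < mu_percentile`.
#' @return list with `cv_threshold`, `mu_threshold`, `cv_percentile`,
#'   `mu_percentile`, and the order-statistic indices `k_cv`, `k_mu`.
#' @export
percentile_thresholds <- function(pseudo, cv_percentile, mu_percentile) {
  if (!nrow(pseudo)) stop("empty pseudo gene set")
  stopifnot(cv_percentile > 0, mu_percentile < 1,
            cv_percentile < mu_percentile)
  n <- nrow(pseudo)
  k_mu <- order_stat_index(mu_percentile, n)
  k_cv <- order_stat_index(cv_percentile, n)
  list(cv_threshold = sort(pseudo$cv)[k_cv],
       mu_threshold = sort(pseudo$mean)[k_mu],
       cv_percentile = cv_percentile, mu_percentile = mu_percentile,
       k_cv = k_cv, k_mu = k_mu)
}

#' Select candidate reference genes against a threshold pair
#'
#' Keeps genes with mean strictly above the mean threshold AND CV strictly
#' below the CV threshold; the result is ordered by ascending CV. Genes
#' sitting exactly on a threshold are reported in the `boundary` element
#' rather than silently included or dropped.
#'
#' @param stats a [gene_stats()] table.
#' @param thr a threshold pair from [percentile_thresholds()] (any list with
#'   `cv_threshold` and `mu_threshold`).
#' @return object of class `threshold_result`: list with `cv_percentile`,
#'   `mu_percentile`, `cv_threshold`, `mu_threshold`, `selected` (gene ids,
#'   CV-ascending), `n_selected`, `boundary` (gene ids on a threshold).
#' @export
select_candidates <- function(stats, thr) {
  if (!nrow(stats)) stop("empty gene_stats table")
  ok <- !is.na(stats$cv) & stats$mean > thr$mu_threshold &
    stats$cv < thr$cv_threshold
  sel <- stats[ok, , drop = FALSE]
  sel <- sel[order(sel$cv, -sel$mean, sel$gene_id), , drop = FALSE]
  on_edge <- !is.na(stats$cv) &
    (stats$mean == thr$mu_threshold | stats$cv == thr$cv_threshold)
  structure(list(cv_percentile = thr$cv_percentile %||% NA_real_,
                 mu_percentile = thr$mu_percentile %||% NA_real_,
                 cv_threshold = thr$cv_threshold,
                 mu_threshold = thr$mu_threshold,
                 selected = sel$gene_id,
                 n_selected = nrow(sel),
                 boundary = stats$gene_id[on_edge]),
            class = "threshold_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result: cv < %.4g (p=%.3g), mean > %.6g (p=%.3g) -> %d gene(s)\n",
    x$cv_threshold, x$cv_percentile, x$mu_threshold, x$mu_percentile,
    x$n_selected))
  invisible(x)
}

#' Run the selection over a ladder of percentile pairs
#'
#' Simulates ONE shared pseudo-gene set and applies every configured
#' percentile pair to it, so the selections are nested: tightening the
#' percentiles can only remove genes. Mirrors the published threshold table
#' where increasingly stringent pairs keep 34, 19, 4 and finally 0 genes.
#'
#' @param x a [count_matrix()].
#' @param stats optional precomputed [gene_stats()] for `x`.
#' @param cfg a [run_config()]; uses `n_pseudo`, `percentile_pairs`, `seed`.
#' @return object of class `threshold_sweep`: list with `pseudo` (the
#'   shared pseudo-gene set), `results` (one [select_candidates()] result
#'   per pair) and `table` (data.frame: percentiles, thresholds,
#'   n_selected).
#' @export
threshold_sweep <- function(x, stats = NULL, cfg = run_config()) {
  if (is.null(stats)) stats <- gene_stats(x)
  pseudo <- simulate_pseudo_genes(x, n_pseudo = cfg$n_pseudo, seed = cfg$seed)
  results <- lapply(cfg$percentile_pairs, function(p) {
    thr <- percentile_thresholds(pseudo, p[1L], p[2L])
    select_candidates(stats, thr)
  })
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(cv_percentile = r$cv_percentile,
               mu_percentile = r$mu_percentile,
               cv_threshold = r$cv_threshold,
               mu_threshold = r$mu_threshold,
               n_selected = r$n_selected)
  }))
  structure(list(pseudo = pseudo, results = results, table = tab),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("threshold_sweep over", nrow(x$table), "percentile pair(s):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
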