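#' Per-gene descriptive statistics across samples
#'
#' Computes, for every gene, the total read count, mean, variance, standard
#' deviation and coefficient of variation (CV = SD / mean) across all
#' samples. These are the two screening statistics of the selection
#' procedure: candidate reference genes must combine a high mean (abundant,
#' hence robust to sampling error) with a low CV (stable across genotypes,
#' stages and treatments).
#'
#' @param x a [count_matrix()] or a numeric matrix (genes x samples).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @return data.frame of class `gene_stats` with columns `gene_id`, `total`,
#'   `mean`, `var`, `sd`, `cv`. Genes with mean 0 get `cv = NA` and are kept.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
#' gene_stats(m)
#' @export
gene_stats <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  n <- ncol(m)
  total <- rowSums(m)
  mu <- total / n
  v <- apply(m, 1L, stats::var)           # n-1 denominator
  if (sd_type == "population") v <- v * (n - 1) / n
  s <- sqrt(v)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  if (anyNA(cv))
    warning(sum(is.na(cv)), " gene(s) with mean 0: cv undefined")
  out <- data.frame(gene_id = rownames(m), total = total, mean = mu,
                    var = v, sd = s, cv = cv,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Five-number summaries of the gene statistics
#'
#' Minimum, first quartile, median, third quartile and maximum of the
#' per-gene mean, variance and CV, using linear-interpolation quantiles
#' (R's default type 7).
#'
#' @param stats a [gene_stats()] table.
#' @return data.frame with columns `stat`, `min`, `q1`, `median`, `q3`,
#'   `max`, one row each for `mean`, `var` and `cv`.
#' @export
describe_stats <- function(stats) {
  if (!nrow(stats)) stop("empty gene_stats table")
  five <- function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE,
                         names = FALSE)
    stats::setNames(as.list(q), c("min", "q1", "median", "q3", "max"))
  }
  rows <- lapply(c(mean = "mean", var = "var", cv = "cv"),
                 function(col) as.data.frame(five(stats[[col]])))
  out <- do.call(rbind, rows)
  out <- cbind(stat = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Pearson correlations among the gene statistics
#'
#' Correlates mean, variance and CV across genes, with two-sided p-values
#' from the t statistic `r * sqrt(n-2) / sqrt(1-r^2)` and conventional
#' significance codes (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `n.s.` otherwise). Under count models where variance grows with the mean
#' (Poisson, quasi-Poisson, negative binomial), mean and variance correlate
#' strongly while the CV is approximately mean-free, which is what makes the
#' CV the useful stability statistic.
#'
#' @param stats a [gene_stats()] table with >= 3 genes.
#' @return data.frame with columns `stat_a`, `stat_b`, `r`, `p`, `code`.
#' @export
stat_correlations <- function(stats) {
  if (nrow(stats) < 3L) stop("need at least 3 genes")
  cols <- c("mean", "var", "cv")
  pairs <- utils::combn(cols, 2L)
  n_all <- nrow(stats)
  rows <- apply(pairs, 2L, function(pr) {
    keep <- stats::complete.cases(stats[pr])
    x <- stats[[pr[1L]]][keep]; y <- stats[[pr[2L]]][keep]
    n <- length(x)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      r <- stats::cor(x, y)
      tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
      p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
    data.frame(stat_a = pr[1L], stat_b = pr[2L], r = r, p = p,
               code = sig_code(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sig_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Rank genes by coefficient of variation
#'
#' Ascending by CV; ties broken by descending mean, then by gene id, so the
#' ordering is deterministic. Genes with undefined CV (mean 0) are dropped
#' with a warning.
#'
#' @param stats a [gene_stats()] table.
#' @return the table reordered, with a `rank` column prepended.
#' @export
rank_by_cv <- function(stats) {
  undef <- is.na(stats$cv)
  if (any(undef)) {
    warning("dropping ", sum(undef), " gene(s) with undefined cv from ranking")
    stats <- stats[!undef, , drop = FALSE]
  }
  ord <- order(stats$cv, -stats$mean, stats$gene_id)
  out <- stats[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
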