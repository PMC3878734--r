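#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Ct on log10 input quantity over a dilution
#' series. The slope of a perfect doubling reaction is -1/log10(2) =
#' -3.3219; in general `E = 10^(-1/slope) - 1`, reported together with the
#' fit's r-squared.
#'
#' @param log10_quantity log10 of the dilution-series input quantities
#'   (>= 3 distinct values).
#' @param ct observed Ct per dilution point.
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency` and the input data.
#' @examples
#' lq <- 0:-4
#' fit_standard_curve(lq, 20 - lq / log10(2))  # perfect doubling, E = 1
#' @export
fit_standard_curve <- function(log10_quantity, ct) {
  stopifnot(length(log10_quantity) == length(ct))
  if (length(unique(log10_quantity)) < 3L)
    stop("need at least 3 distinct dilution points")
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative")
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 log10_quantity = log10_quantity, ct = ct),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, E = %.1f%%, r2 = %.4f\n",
              x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Check an amplification efficiency against the accepted range
#'
#' Primer pairs with efficiencies between 83% and 110% (inclusive) are
#' considered acceptable for quantification; values outside — e.g. a 129%
#' efficiency, which usually signals inhibitors or primer artefacts — are
#' flagged.
#'
#' @param efficiency efficiency on the proportion scale (1 = 100%).
#' @param range acceptance bounds, default `c(0.83, 1.10)`.
#' @return `"in_range"` or `"out_of_range"` (vectorized).
#' @export
efficiency_check <- function(efficiency, range = c(0.83, 1.10)) {
  stopifnot(all(efficiency >= 0))
  ifelse(efficiency >= range[1L] & efficiency <= range[2L],
         "in_range", "out_of_range")
}

#' Per-gene variability of raw Ct values
#'
#' Five-number summary (linear-interpolation quantiles, the same convention
#' as [describe_stats()]) plus the CV of raw Ct per gene, the box-plot view
#' of how tightly each candidate's threshold cycle sits across samples.
#' Stable, abundant reference genes typically show Ct CVs of a few percent.
#'
#' @param ct Ct matrix, genes x samples, NA = missing.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return data.frame with columns `gene_id`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `cv`. Genes with < 2 non-missing values are excluded with
#'   a warning.
#' @export
ct_variability <- function(ct, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ct <- as.matrix(ct)
  n_ok <- rowSums(!is.na(ct))
  if (any(n_ok < 2L)) {
    warning("excluding ", sum(n_ok < 2L), " gene(s) with < 2 Ct values")
    ct <- ct[n_ok >= 2L, , drop = FALSE]
  }
  rows <- lapply(rownames(ct), function(g) {
    v <- ct[g, ]; v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    s <- stats::sd(v)
    if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
    data.frame(gene_id = g, n = length(v), min = q[1L], q1 = q[2L],
               median = q[3L], q3 = q[4L], max = q[5L], cv = s / mean(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression profiles by sample group
#'
#' Group means and standard errors of relative quantities, each gene scaled
#' so that its lowest group mean equals 1 (expression relative to the
#' lowest-expressing condition). Alternatively, scale every gene by a
#' designated reference gene's group means.
#'
#' @param q strictly positive quantity matrix, genes x samples.
#' @param groups character/factor of group labels, one per sample (must
#'   partition the columns).
#' @param reference_gene optional gene id; when given, each gene's group
#'   means are divided by this gene's group means instead of by the gene's
#'   own minimum.
#' @return data.frame with columns `gene_id`, `group`, `mean`, `se`,
#'   `relative` (scaled mean), `relative_se`.
#' @export
relative_expression <- function(q, groups, reference_gene = NULL) {
  q <- as.matrix(q)
  if (length(groups) != ncol(q))
    stop("groups must have one label per sample")
  groups <- as.character(groups)
  if (any(table(groups) < 1L)) stop("empty group")
  levs <- unique(groups)
  fg <- factor(groups, levs)
  gm <- do.call(rbind, lapply(rownames(q), function(g)
    tapply(q[g, ], fg, mean)))
  gse <- do.call(rbind, lapply(rownames(q), function(g)
    tapply(q[g, ], fg, function(z) {
      if (length(z) < 2L) return(NA_real_)
      stats::sd(z) / sqrt(length(z))
    })))
  rownames(gm) <- rownames(gse) <- rownames(q)
  denom <- if (is.null(reference_gene)) {
    apply(gm, 1L, min)
  } else {
    if (!reference_gene %in% rownames(q)) stop("unknown reference gene")
    # per-group scaling by the reference profile
    NULL
  }
  rows <- lapply(rownames(q), function(g) {
    sc <- if (is.null(reference_gene)) denom[g] else gm[reference_gene, ]
    data.frame(gene_id = g, group = levs,
               mean = as.numeric(gm[g, ]), se = as.numeric(gse[g, ]),
               relative = as.numeric(gm[g, ] / sc),
               relative_se = as.numeric(gse[g, ] / sc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
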