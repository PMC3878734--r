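#' Transform Ct values to relative quantities
#'
#' Applies the standard-curve transform required by geNorm-type stability
#' analysis: per gene, `quantity = (1 + E)^(Ct_min - Ct)`, so the
#' highest-expressed sample (lowest Ct) becomes the calibrator with
#' quantity 1 and every extra cycle divides the quantity by `1 + E`.
#' Genes with fewer than 2 non-missing Ct values are excluded with a
#' warning; missing cells stay `NA` and are dropped pairwise downstream.
#'
#' @param ct numeric matrix of Ct values, genes x samples (NA = missing).
#' @param efficiencies per-gene amplification efficiency in (0, 2];
#'   recycled if length 1. A named vector is matched to `rownames(ct)`.
#' @return matrix of relative quantities with the input dimnames.
#' @examples
#' ct <- rbind(gA = c(20, 21, 22), gB = c(24, 24, 24))
#' ct_to_quantity(ct, efficiencies = 1)
#' @export
ct_to_quantity <- function(ct, efficiencies = 1) {
  ct <- as.matrix(ct)
  if (any(!is.finite(ct) & !is.na(ct))) stop("Ct values must be finite or NA")
  if (any(efficiencies <= 0) || any(efficiencies > 2))
    stop("efficiencies must be in (0, 2]")
  if (!is.null(names(efficiencies)) && !is.null(rownames(ct))) {
    if (!all(rownames(ct) %in% names(efficiencies)))
      stop("efficiencies missing for some genes")
    efficiencies <- efficiencies[rownames(ct)]
  } else {
    efficiencies <- rep_len(efficiencies, nrow(ct))
  }
  ok <- rowSums(!is.na(ct)) >= 2L
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " gene(s) with < 2 non-missing Ct values")
    ct <- ct[ok, , drop = FALSE]
    efficiencies <- efficiencies[ok]
  }
  q <- ct
  for (i in seq_len(nrow(ct))) {
    cmin <- min(ct[i, ], na.rm = TRUE)
    q[i, ] <- (1 + efficiencies[i])^(cmin - ct[i, ])
  }
  q
}

#' Pairwise variation between two genes
#'
#' The geNorm building block: the standard deviation, across samples, of
#' the log2 ratio of the two genes' relative quantities. Two ideal
#' reference genes track each other perfectly and have pairwise variation 0
#' regardless of the samples' overall expression levels.
#'
#' @param q strictly positive quantity matrix, genes x samples.
#' @param gene_j,gene_k gene ids (rownames of `q`).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return V_jk >= 0.
#' @export
pairwise_sd <- function(q, gene_j, gene_k, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(gene_j %in% rownames(q), gene_k %in% rownames(q))
  lr <- log2(q[gene_j, ] / q[gene_k, ])
  lr <- lr[is.finite(lr)]
  if (length(lr) < 2L) stop("need >= 2 samples with both genes measured")
  if (any(q[gene_j, ] <= 0, na.rm = TRUE) || any(q[gene_k, ] <= 0, na.rm = TRUE))
    stop("quantities must be strictly positive")
  v <- stats::sd(lr)
  if (sd_type == "population") v <- v * sqrt((length(lr) - 1) / length(lr))
  v
}

#' geNorm expression-stability measure M
#'
#' M of a gene is the arithmetic mean of its pairwise variations
#' [pairwise_sd()] with every other gene in the set; lower M = more stable.
#'
#' @param q strictly positive quantity matrix with >= 2 genes.
#' @param genes optional subset of gene ids (default all).
#' @inheritParams pairwise_sd
#' @return named numeric vector of M values, one per gene.
#' @export
m_values <- function(q, genes = rownames(q), sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(genes) < 2L) stop("M needs at least 2 genes")
  vapply(genes, function(j) {
    mean(vapply(setdiff(genes, j),
                function(k) pairwise_sd(q, j, k, sd_type), numeric(1L)))
  }, numeric(1L))
}

#' geNorm stability ranking by stepwise exclusion
#'
#' Iteratively computes M for all remaining genes and removes the single
#' least stable gene (maximal M; ties broken by gene id, and logged via a
#' message) until two genes remain. Those two form the most stable pair;
#' their final M values are identical by construction, so the pair is
#' unordered.
#'
#' @param q strictly positive quantity matrix with >= 3 genes.
#' @inheritParams pairwise_sd
#' @return object of class `stability_ranking`: list with `rounds` (one
#'   entry per exclusion round: `genes`, `m`, `excluded`), `final_pair`,
#'   `exclusion_order` (least stable first), `ranking` (most stable first;
#'   the final pair ranks 1-2 alphabetically) and `m_trace` (data.frame of
#'   the average M at each round, the classic stepwise-exclusion plot).
#' @export
stepwise_ranking <- function(q, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  q <- as.matrix(q)
  if (nrow(q) < 3L) stop("stepwise ranking needs at least 3 genes")
  remaining <- rownames(q)
  rounds <- list()
  excluded <- character(0)
  while (length(remaining) > 2L) {
    m <- m_values(q, remaining, sd_type)
    worst <- names(m)[m == max(m)]
    if (length(worst) > 1L) {
      worst <- sort(worst)
      message("M tie between ", paste(worst, collapse = ", "),
              "; excluding ", worst[1L])
    }
    out <- worst[1L]
    rounds[[length(rounds) + 1L]] <-
      list(genes = remaining, m = as.list(m), excluded = out)
    excluded <- c(excluded, out)
    remaining <- setdiff(remaining, out)
  }
  m_final <- m_values(q, remaining, sd_type)
  rounds[[length(rounds) + 1L]] <-
    list(genes = remaining, m = as.list(m_final), excluded = NA_character_)
  m_trace <- data.frame(
    round = seq_along(rounds),
    n_genes = vapply(rounds, function(r) length(r$genes), integer(1L)),
    mean_m = vapply(rounds, function(r) mean(unlist(r$m)), numeric(1L)),
    excluded = vapply(rounds, function(r) r$excluded, character(1L)))
  structure(list(rounds = rounds,
                 final_pair = sort(remaining),
                 exclusion_order = excluded,
                 ranking = c(sort(remaining), rev(excluded)),
                 m_trace = m_trace),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("stability_ranking:", length(x$ranking), "gene(s),",
      length(x$exclusion_order), "exclusion round(s)\n")
  cat("most stable pair:", paste(x$final_pair, collapse = " + "), "\n")
  invisible(x)
}

#' geNorm pairwise-variation statistic V(n / n+1)
#'
#' Optional companion to the M ranking: for each n, the standard deviation
#' across samples of the log2 ratio of normalization factors (geometric
#' means of quantities) computed from the n and the n+1 most stable genes.
#' Small V (conventionally < 0.15) indicates that adding the (n+1)-th gene
#' does not change the normalization factor materially.
#'
#' @param q strictly positive quantity matrix.
#' @param ranking a [stepwise_ranking()] result for `q`.
#' @return data.frame with columns `n`, `v` for n = 2 .. (genes - 1).
#' @export
pairwise_variation <- function(q, ranking = stepwise_ranking(q)) {
  ord <- ranking$ranking
  if (length(ord) < 3L) stop("pairwise variation needs >= 3 genes")
  nf <- function(genes) exp(colMeans(log(q[genes, , drop = FALSE])))
  rows <- lapply(2:(length(ord) - 1L), function(n) {
    v <- stats::sd(log2(nf(ord[seq_len(n)]) / nf(ord[seq_len(n + 1L)])))
    data.frame(n = n, v = v)
  })
  do.call(rbind, rows)
}
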