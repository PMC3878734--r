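#' Configuration for the synthetic RNA-Seq study
#'
#' The defaults emulate the structure of the study the pipeline was built
#' for: 47 berry samples from 14 table-grape genotypes spread over 4
#' phenological/treatment conditions, with gene base means spanning roughly
#' 330-3,700 reads. Three gene classes are planted: `stable` genes
#' (housekeeping behaviour: fold change 1 in every condition, low
#' dispersion), `de` genes (condition-dependent fold changes) and `noisy`
#' genes (fold change 1 but high biological dispersion).
#'
#' @param n_samples number of samples (default 47).
#' @param n_conditions number of experimental conditions (default 4).
#' @param n_genotypes number of genotypes cycled over samples (default 14).
#' @param n_stable,n_de,n_noisy genes per class.
#' @param mean_range `c(low, high)` range of expected per-sample reads;
#'   base means are drawn log-uniformly inside it (default 330-3,700).
#' @param dispersion_stable,dispersion_noisy negative-binomial dispersion
#'   phi (variance = mu + phi * mu^2) for the stable/DE and noisy classes.
#' @param de_log2fc absolute log2 fold change applied to DE genes in a
#'   randomly chosen half of the conditions.
#' @param libsize_sd standard deviation (log scale) of per-sample library
#'   size factors; 0 gives equal depths. Factors are normalized to
#'   geometric mean 1.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 47L, n_conditions = 4L, n_genotypes = 14L,
                       n_stable = 20L, n_de = 60L, n_noisy = 120L,
                       mean_range = c(330, 3700),
                       dispersion_stable = 0.05, dispersion_noisy = 0.6,
                       de_log2fc = 2.0, libsize_sd = 0.2, seed = 1L) {
  stopifnot(n_samples >= 2L, n_conditions >= 1L, n_genotypes >= 1L,
            n_stable >= 0L, n_de >= 0L, n_noisy >= 0L,
            length(mean_range) == 2L, mean_range[1L] > 0,
            mean_range[1L] < mean_range[2L],
            dispersion_stable >= 0, dispersion_noisy >= 0,
            libsize_sd >= 0)
  if (n_stable + n_de + n_noisy < 1L)
    stop("at least one gene must be requested")
  structure(list(n_samples = as.integer(n_samples),
                 n_conditions = as.integer(n_conditions),
                 n_genotypes = as.integer(n_genotypes),
                 n_stable = as.integer(n_stable), n_de = as.integer(n_de),
                 n_noisy = as.integer(n_noisy), mean_range = mean_range,
                 dispersion_stable = dispersion_stable,
                 dispersion_noisy = dispersion_noisy,
                 de_log2fc = de_log2fc, libsize_sd = libsize_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draw with variance mu + phi mu^2; phi = 0 degenerates to Poisson
rnb <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a count matrix with planted gene classes
#'
#' Counts are drawn from a negative binomial with mean
#' `base_mean * size_factor * condition_fold_change` and class-specific
#' dispersion (variance = mu + phi * mu^2). Stable and noisy genes have fold
#' change 1 in every condition; DE genes get a +/- `de_log2fc` log2 shift in
#' half of the conditions. Samples are assigned round-robin to genotypes and
#' in contiguous blocks to conditions.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data.frame: `gene_id`, `class`, `base_mean`, `dispersion`, and one
#'   `fc_<condition>` column per condition with the true fold change).
#' @examples
#' sim <- simulate_counts(sim_config(n_stable = 5, n_de = 5, n_noisy = 2,
#'                                   n_samples = 12, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, "counts"))
  n_genes <- cfg$n_stable + cfg$n_de + cfg$n_noisy
  classes <- rep(c("stable", "de", "noisy"),
                 c(cfg$n_stable, cfg$n_de, cfg$n_noisy))
  gene_ids <- sprintf("gene%04d_%s", seq_len(n_genes), classes)

  cond_labels <- sprintf("cond%d", seq_len(cfg$n_conditions))
  condition <- cond_labels[ceiling(seq_len(cfg$n_samples) /
                                     (cfg$n_samples / cfg$n_conditions))]
  genotype <- sprintf("geno%02d",
                      rep_len(seq_len(cfg$n_genotypes), cfg$n_samples))
  design <- data.frame(sample_id = sprintf("s%02d", seq_len(cfg$n_samples)),
                       genotype = genotype,
                       stage = condition,
                       treatment = "none",
                       condition = condition,
                       stringsAsFactors = FALSE)

  base_mean <- exp(stats::runif(n_genes, log(cfg$mean_range[1L]),
                                log(cfg$mean_range[2L])))
  dispersion <- ifelse(classes == "noisy", cfg$dispersion_noisy,
                       cfg$dispersion_stable)

  # per-gene x condition fold changes; DE genes shifted in half the conditions
  fc <- matrix(1, n_genes, cfg$n_conditions,
               dimnames = list(gene_ids, cond_labels))
  de_idx <- which(classes == "de")
  n_up <- max(1L, floor(cfg$n_conditions / 2))
  for (i in de_idx) {
    shifted <- sample.int(cfg$n_conditions, n_up)
    fc[i, shifted] <- 2^(sample(c(-1, 1), 1) * cfg$de_log2fc)
  }

  sf <- if (cfg$libsize_sd > 0) {
    raw <- exp(stats::rnorm(cfg$n_samples, 0, cfg$libsize_sd))
    raw / exp(mean(log(raw)))
  } else rep(1, cfg$n_samples)

  counts <- matrix(0L, n_genes, cfg$n_samples,
                   dimnames = list(gene_ids, design$sample_id))
  cond_idx <- match(condition, cond_labels)
  for (i in seq_len(n_genes)) {
    mu <- base_mean[i] * sf * fc[i, cond_idx]
    counts[i, ] <- rnb(cfg$n_samples, mu, dispersion[i])
  }

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      base_mean = base_mean, dispersion = dispersion,
                      stringsAsFactors = FALSE)
  colnames(fc) <- paste0("fc_", cond_labels)
  truth <- cbind(truth, as.data.frame(fc))
  rownames(truth) <- NULL
  list(counts = count_matrix(counts, design), truth = truth,
       size_factors = stats::setNames(sf, design$sample_id))
}

#' Simulate a Ct table from true expression quantities
#'
#' Inverts the standard-curve transform used in qPCR analysis: a sample with
#' relative quantity q amplifies `log(q)/log(1+E)` cycles earlier than the
#' reference point, so `Ct = ct_ref - log(q)/log(1+E) + noise`.
#'
#' @param quantities strictly positive matrix of true relative expression,
#'   genes x samples.
#' @param efficiency per-gene amplification efficiency in (0, 2]; recycled
#'   if length 1.
#' @param ct_noise_sd Gaussian technical noise on Ct, in cycles; recycled
#'   per gene.
#' @param ct_ref baseline Ct assigned to quantity 1 (default 21, a typical
#'   mid-range threshold cycle); recycled per gene.
#' @param seed integer seed.
#' @return numeric matrix of Ct values with the input dimnames.
#' @examples
#' q <- matrix(c(1, 2, 4, 1, 1, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
#' simulate_ct(q, efficiency = 1, ct_noise_sd = 0)
#' @export
simulate_ct <- function(quantities, efficiency = 1, ct_noise_sd = 0.3,
                        ct_ref = 21, seed = 1L) {
  quantities <- as.matrix(quantities)
  if (any(quantities <= 0) || anyNA(quantities))
    stop("quantities must be strictly positive")
  if (any(efficiency <= 0) || any(efficiency > 2))
    stop("efficiency must be in (0, 2]")
  if (any(ct_noise_sd < 0)) stop("ct_noise_sd must be >= 0")
  n_genes <- nrow(quantities)
  efficiency <- rep_len(efficiency, n_genes)
  ct_noise_sd <- rep_len(ct_noise_sd, n_genes)
  ct_ref <- rep_len(ct_ref, n_genes)
  set.seed(child_seed(seed, "ct"))
  ct <- quantities
  for (i in seq_len(n_genes)) {
    ct[i, ] <- ct_ref[i] - log(quantities[i, ]) / log(1 + efficiency[i]) +
      stats::rnorm(ncol(quantities), 0, ct_noise_sd[i])
  }
  ct
}
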