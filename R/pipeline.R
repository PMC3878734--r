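#' Run the full reference-gene selection pipeline
#'
#' Orchestrates the stages end to end: (1) NDE filtering of the count
#' matrix across all pairwise condition comparisons, (2) per-gene
#' statistics on the surviving genes, (3) pooled-resampling percentile
#' thresholds and candidate selection over the configured percentile
#' ladder, and (4) optionally, geNorm stability ranking of the candidates
#' on a Ct table. All stage outputs are written as plain CSV/JSON files so
#' stages can be rerun or inspected independently, and a machine-readable
#' manifest records the configuration, seed, file checksums and the gene
#' funnel (input genes >= NDE genes >= selected candidates).
#'
#' @param x a [count_matrix()], or a [sim_config()] to simulate one.
#' @param cfg a [run_config()].
#' @param ct optional Ct matrix (genes x samples) for the validation stage;
#'   rows are matched to selected candidates when possible, otherwise used
#'   as-is. If `x` is a `sim_config` and `ct = "simulate"`, a Ct table for
#'   the selected candidates is simulated from their scaled counts.
#' @param efficiencies per-gene amplification efficiencies for
#'   [ct_to_quantity()] (default 1).
#' @param out_dir directory for stage reports (created if needed); `NULL`
#'   skips writing.
#' @return object of class `run_manifest`: list with `config`, `seed`,
#'   `stage_counts`, `files` (paths + md5 checksums), `nde`, `stats`,
#'   `sweep`, and `stability` (NULL when no Ct stage ran).
#' @export
run_pipeline <- function(x, cfg = run_config(), ct = NULL,
                         efficiencies = 1, out_dir = NULL) {
  truth <- NULL
  if (inherits(x, "sim_config")) {
    sim <- simulate_counts(x)
    cm <- sim$counts
    truth <- sim$truth
  } else {
    stopifnot(inherits(x, "count_matrix"))
    cm <- x
  }

  nde <- select_nde(cm, cfg)
  if (!length(nde$gene_ids))
    stop("nde_filter: no gene passed the NDE and minimum-reads filters")
  cm_nde <- count_matrix(cm$counts[nde$gene_ids, , drop = FALSE], cm$design,
                         integer_counts = FALSE)
  stats <- gene_stats(cm_nde)
  sweep <- threshold_sweep(cm_nde, stats, cfg)

  # validation stage: geNorm on the last non-empty selection
  n_sel <- sweep$table$n_selected
  pick <- which(n_sel >= 3L)
  candidates <- if (length(pick)) sweep$results[[max(pick)]]$selected else character(0)

  stability <- NULL
  ct_used <- NULL
  if (!is.null(ct)) {
    if (identical(ct, "simulate")) {
      if (length(candidates) >= 3L) {
        qtrue <- sweep_quantities(cm_nde, candidates)
        ct_used <- simulate_ct(qtrue, efficiency = efficiencies,
                               ct_noise_sd = 0.3, seed = cfg$seed)
      }
    } else {
      ct_used <- as.matrix(ct)
      common <- intersect(rownames(ct_used), candidates)
      if (length(common) >= 3L)
        ct_used <- ct_used[common, , drop = FALSE]
    }
    if (!is.null(ct_used) && nrow(ct_used) >= 3L) {
      q <- ct_to_quantity(ct_used, efficiencies)
      stability <- stepwise_ranking(q)
    }
  }

  stage_counts <- c(input = nrow(cm$counts),
                    nde = length(nde$gene_ids),
                    selected = if (length(n_sel)) max(n_sel) else 0L,
                    ranked = if (is.null(stability)) NA_integer_
                             else length(stability$ranking))

  files <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(out_dir, name)
    write_report(stats, out("gene_stats.csv"))
    write_report(data.frame(gene_id = nde$gene_ids), out("nde_genes.csv"))
    write_report(nde$de_table, out("de_table.csv"))
    write_report(sweep$table, out("threshold_table.csv"))
    write_report(rank_by_cv(stats), out("cv_ranking.csv"))
    if (!is.null(truth)) write_report(truth, out("truth_labels.csv"))
    if (!is.null(stability)) {
      write_report(stability, out("stability_ranking.json"))
      write_report(stability$m_trace, out("m_trace.csv"))
    }
    paths <- list.files(out_dir, full.names = TRUE)
    files <- as.list(tools::md5sum(paths))
    names(files) <- basename(paths)
  }

  manifest <- structure(list(config = unclass(cfg),
                             seed = cfg$seed,
                             stage_counts = as.list(stage_counts),
                             files = files,
                             nde = nde, stats = stats, sweep = sweep,
                             stability = stability, truth = truth),
                        class = "run_manifest")
  if (!is.null(out_dir)) {
    slim <- list(config = unclass(cfg), seed = cfg$seed,
                 stage_counts = as.list(stage_counts),
                 n_comparisons = nde$n_comparisons,
                 files = files,
                 package_version = as.character(utils::packageVersion("refstab")))
    jsonlite::write_json(slim, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}

# true relative quantities for the Ct simulation: size-factor-scaled counts,
# floored at 0.5 to stay strictly positive
sweep_quantities <- function(cm, genes) {
  m <- cm$counts[genes, , drop = FALSE]
  sf <- colSums(cm$counts); sf <- sf / mean(sf)
  q <- sweep(m, 2L, sf, "/")
  pmax(q, 0.5)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (seed", x$seed, ")\n")
  sc <- x$stage_counts
  cat(sprintf("  genes: %d input -> %d NDE -> %d selected\n",
              sc$input, sc$nde, sc$selected))
  if (!is.null(x$stability))
    cat("  most stable pair:", paste(x$stability$final_pair, collapse = " + "),
        "\n")
  invisible(x)
}
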