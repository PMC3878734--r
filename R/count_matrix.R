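#' Construct a validated count matrix with its sample design
#'
#' Bundles a genes x samples matrix of non-negative read counts with a
#' per-sample design table (genotype, phenological stage, treatment). All
#' downstream stages of the pipeline consume this container.
#'
#' @param counts numeric matrix, genes in rows and samples in columns, with
#'   row and column names. Entries must be non-negative; integer-valued
#'   entries are required when `integer_counts = TRUE` (the default for data
#'   read from files).
#' @param design data.frame with one row per sample and at least a
#'   `sample_id` column; conventional columns are `genotype`, `stage` and
#'   `treatment`. An optional `condition` column overrides the default
#'   stage-by-treatment condition labels (see [sample_conditions()]).
#' @param integer_counts logical; enforce integer-valued counts.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `design` (the data.frame, ordered as the columns).
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 12L, 18L, 33L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' d <- data.frame(sample_id = c("s1", "s2", "s3"), genotype = "G1",
#'                 stage = c("anthesis", "anthesis", "berry"),
#'                 treatment = "none")
#' cm <- count_matrix(m, d)
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, design, integer_counts = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and sample (column) names")
  if (nrow(counts) < 1L) stop("need at least 1 gene")
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (integer_counts && any(counts != round(counts)))
    stop("counts must be integer-valued")
  design <- as.data.frame(design)
  if (!"sample_id" %in% names(design))
    stop("design must have a 'sample_id' column")
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  conds <- table(sample_conditions(x))
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(conds), as.integer(conds)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Condition label per sample
#'
#' Returns the experimental condition of every sample: the `condition`
#' column of the design when present, otherwise the stage x treatment
#' interaction (so a treated and an untreated sample at the same stage fall
#' in different conditions).
#'
#' @param x a `count_matrix`.
#' @return character vector, one label per sample, in column order.
#' @export
sample_conditions <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  d <- x$design
  if ("condition" %in% names(d)) return(as.character(d$condition))
  parts <- d[intersect(c("stage", "treatment"), names(d))]
  if (!ncol(parts))
    stop("design has neither a 'condition' column nor stage/treatment columns")
  labs <- do.call(paste, c(lapply(parts, as.character), sep = ":"))
  as.character(labs)
}

#' Read a count matrix and its design table from delimited text
#'
#' The counts file has a header row of sample ids, gene ids in the first
#' column, and one row per gene. The design file is tab-separated with
#' columns `sample_id`, `genotype`, `stage`, `treatment` (extra columns are
#' kept). Delimiter for the counts file is inferred from the extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path counts file.
#' @param design_path design table file.
#' @return a validated [count_matrix()].
#' @export
read_count_matrix <- function(path, design_path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (!file.exists(design_path)) stop("design file not found: ", design_path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 3L) stop("counts file needs a gene-id column and >= 2 samples")
  gene_ids <- tab[[1L]]
  num <- tab[, -1L, drop = FALSE]
  parsed <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  if (nrow(num) == 1L) parsed <- matrix(parsed, nrow = 1L, dimnames = list(NULL, names(num)))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop(sprintf("cannot parse count at row %d (gene '%s'), column '%s'",
                 bad[1L], gene_ids[bad[1L]], colnames(parsed)[bad[2L]]))
  }
  rownames(parsed) <- gene_ids
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(parsed, design)
}

#' Write a count matrix (and its design) to tab-separated files
#'
#' @param x a `count_matrix`.
#' @param path counts TSV to write (first column `gene_id`).
#' @param design_path optional design TSV to write.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read / write a Ct table
#'
#' Ct tables are tab-separated, genes in rows (first column `gene_id`),
#' samples in columns; missing Ct values are empty cells.
#'
#' @param path file path.
#' @return numeric matrix of Ct values (NA = missing).
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}

#' @rdname read_ct_table
#' @param ct numeric matrix of Ct values, genes x samples.
#' @export
write_ct_table <- function(ct, path) {
  tab <- data.frame(gene_id = rownames(ct), ct, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Holds the tunable parameters of the selection pipeline. Defaults follow
#' the published procedure: 10,000 pseudo genes, the four percentile pairs
#' (5/95, 2.5/97.5, 1/99, 0.1/99.9), a minimum of 100 reads in every sample,
#' and a 5% significance level for the differential-expression filter.
#'
#' @param n_pseudo number of pseudo genes to resample.
#' @param percentile_pairs list of `c(cv_percentile, mu_percentile)` pairs,
#'   each in (0,1) with cv_percentile < mu_percentile.
#' @param min_reads_per_sample minimum reads required in every sample.
#' @param alpha significance level for the NDE filter.
#' @param cv_cap ceiling on gene CV during NDE filtering — the "variation
#'   index" criterion. Default 0.65, the upper bound observed for accepted
#'   non-differential genes in the grapevine study this pipeline models;
#'   `NULL` disables it. Without a cap, high-dispersion genes surviving the
#'   DE test contaminate the pooled resampling null and inflate both
#'   selection thresholds.
#' @param seed integer seed driving all stochastic stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_pseudo = 10000L,
                       percentile_pairs = list(c(0.05, 0.95), c(0.025, 0.975),
                                               c(0.01, 0.99), c(0.001, 0.999)),
                       min_reads_per_sample = 100L,
                       alpha = 0.05,
                       cv_cap = 0.65,
                       seed = 1L) {
  stopifnot(n_pseudo >= 1L, min_reads_per_sample >= 0L,
            alpha > 0, alpha < 1)
  for (p in percentile_pairs) {
    if (length(p) != 2L || any(p <= 0) || any(p >= 1) || p[1L] >= p[2L])
      stop("each percentile pair must be (cv_percentile, mu_percentile) with ",
           "0 < cv < mu < 1")
  }
  structure(list(n_pseudo = as.integer(n_pseudo),
                 percentile_pairs = percentile_pairs,
                 min_reads_per_sample = as.integer(min_reads_per_sample),
                 alpha = alpha, cv_cap = cv_cap, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a pipeline result to disk
#'
#' Tabular results (data.frames: gene statistics, CV rankings, DE tables)
#' are written as CSV; nested results (threshold results, stability
#' rankings, manifests) as JSON with a deterministic field order. Decimal
#' output always uses `.`.
#'
#' @param results a pipeline result object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.data.frame(results)) {
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(unclass_deep(results), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

# strip S3 classes recursively so jsonlite serializes plain structures
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

# deterministic child seed for a named sub-stream, kept below 2^31
child_seed <- function(seed, what) {
  offs <- c(pool = 11L, counts = 23L, ct = 37L, pipeline = 53L)
  o <- offs[[what]]
  as.integer((as.numeric(seed) * 69069 + o) %% 2147483647)
}
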