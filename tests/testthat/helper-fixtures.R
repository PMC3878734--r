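# small in-code fixtures shared across test files

tiny_counts <- function(values = c(10L, 20L, 30L, 12L, 18L, 33L),
                        n_genes = 2L, n_samples = 3L,
                        stages = c("anthesis", "anthesis", "berry")) {
  m <- matrix(values, nrow = n_genes, byrow = TRUE,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  d <- data.frame(sample_id = colnames(m),
                  genotype = "G1",
                  stage = stages,
                  treatment = "none",
                  stringsAsFactors = FALSE)
  count_matrix(m, d)
}

# a matrix with a prescribed mean and sample SD via affine transform of a
# fixed zero-mean unit-SD vector (exact to floating point)
vector_with_moments <- function(n, mean, sd) {
  z <- seq_len(n) - (n + 1) / 2
  z <- z / stats::sd(z)
  mean + sd * z
}

# independent naive geNorm implementation used as oracle: recompute M from
# first principles each round and drop the max-M gene
naive_genorm <- function(q, sd_type = "sample") {
  sdfun <- function(v) {
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  mfun <- function(genes) {
    vapply(genes, function(j) {
      mean(vapply(setdiff(genes, j),
                  function(k) sdfun(log2(q[j, ] / q[k, ])), numeric(1)))
    }, numeric(1))
  }
  remaining <- rownames(q)
  order_out <- character(0)
  while (length(remaining) > 2) {
    m <- mfun(remaining)
    worst <- sort(names(m)[m == max(m)])[1]
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(final_pair = sort(remaining), exclusion_order = order_out)
}
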