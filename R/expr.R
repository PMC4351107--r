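# expression summarisation: the RPKM arithmetic layer over externally
# produced read counts (no read alignment here), plus a negative-binomial
# count generator for null-scenario fixtures.

#' Reads per kilobase of transcript per million mapped reads
#'
#' \code{count / (length_bp / 1000) / (total_mapped / 1e6)}. Vectorized over
#' \code{count} and \code{length_bp}.
#'
#' @param count raw mapped-read count (>= 0).
#' @param length_bp CDS length in base pairs (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / (length_bp / 1000) / (total_mapped / 1e6)
}

#' RPKM matrix from a count matrix
#'
#' @param counts genes x samples integer matrix.
#' @param lengths_bp per-gene CDS lengths (bp), recycled over columns.
#' @param totals per-sample mapped-read totals; defaults to the column sums.
#' @return matrix of RPKM values with the dimnames of \code{counts}.
#' @export
rpkm_table <- function(counts, lengths_bp, totals = colSums(counts)) {
  if (length(lengths_bp) != nrow(counts))
    stop("one length per gene required")
  if (any(totals < colSums(counts)))
    stop("per-sample totals cannot be below the column sums")
  out <- sweep(counts / (lengths_bp / 1000), 2, totals / 1e6, "/")
  dimnames(out) <- dimnames(counts)
  out
}

#' Log2 fold changes of RPKM against a baseline sample
#'
#' \code{log2((rpkm + pc) / (rpkm_baseline + pc))}; the baseline column is
#' all zeros by construction.
#'
#' @param rpkm_mat genes x samples RPKM matrix.
#' @param baseline baseline sample (column name).
#' @param pseudocount pseudocount in RPKM units.
#' @return matrix of log2 ratios.
#' @export
fold_table <- function(rpkm_mat, baseline, pseudocount = 1) {
  if (!baseline %in% colnames(rpkm_mat))
    stop("baseline sample '", baseline, "' not found")
  log2(sweep(rpkm_mat + pseudocount, 1, rpkm_mat[, baseline] + pseudocount, "/"))
}

#' Simulate a null-scenario count table
#'
#' Negative-binomial counts with a common expected RPKM across samples (no
#' expression change), so RPKM heat tables under the null can be emulated.
#'
#' @param lengths_bp named per-gene CDS lengths (bp).
#' @param samples sample names.
#' @param mean_rpkm expected RPKM, common to all genes and samples.
#' @param dispersion NB dispersion (\code{size = 1/dispersion}).
#' @param depth expected mapped reads per sample.
#' @param seed integer seed.
#' @return genes x samples count matrix.
#' @export
simulate_counts <- function(lengths_bp, samples, mean_rpkm = 30,
                            dispersion = 0.3, depth = 1e6, seed = 1L) {
  set.seed(stage_seed(seed, "expr"))
  mu <- outer(mean_rpkm * (lengths_bp / 1000), rep(depth / 1e6, length(samples)))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = length(lengths_bp),
                   dimnames = list(names(lengths_bp), samples))
  counts
}

#' Write/read an expression table (values fixed at 6 decimals)
#' @param x numeric matrix (genes x samples).
#' @param path file path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(id = rownames(x), round(x, 6), check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
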