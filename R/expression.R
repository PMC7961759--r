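#' Expression matrix container
#'
#' Lightweight container for a genes x samples abundance matrix with an
#' explicit unit tag. Units move only through declared operations:
#' `counts` -> `TPM` via [counts_to_tpm()], `TPM` -> `log2TPM` via
#' [log2_tpm()].
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names must be present and unique.
#' @param unit one of `"counts"`, `"TPM"`, `"log2TPM"`.
#' @param gene_lengths optional named numeric vector of gene lengths in bp
#'   (required later for `counts` -> `TPM`).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `unit`, `gene_lengths`.
#' @examples
#' m <- expr_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'                  unit = "counts", gene_lengths = c(g1 = 1000, g2 = 2000))
#' counts_to_tpm(m)
#' @export
expr_matrix <- function(values, unit = c("counts", "TPM", "log2TPM"),
                        gene_lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids in expression matrix")
  if (unit != "log2TPM" && any(values < 0))
    stopf("negative values are not allowed for unit '%s'", unit)
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) stopf("gene_lengths must be named")
    if (any(gene_lengths <= 0)) stopf("gene_lengths must be positive")
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

as_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
}

#' Convert raw counts to TPM
#'
#' Transcripts per million: each sample's counts are divided by gene length
#' (kb), then scaled so the column sums to 1e6.
#'
#' @param x an [expr_matrix()] with unit `"counts"`.
#' @param lengths named per-gene lengths in bp; defaults to the lengths
#'   stored in `x`.
#' @return An `expr_matrix` with unit `"TPM"`; every column sums to 1e6.
#' @export
counts_to_tpm <- function(x, lengths = x$gene_lengths) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stopf("counts_to_tpm expects unit 'counts', got '%s'", x$unit)
  if (is.null(lengths)) stopf("gene lengths are required for counts -> TPM")
  missing <- setdiff(gene_ids(x), names(lengths))
  if (length(missing))
    stopf("no length for gene(s): %s", paste(head(missing, 5), collapse = ", "))
  len <- lengths[gene_ids(x)]
  if (any(len <= 0)) stopf("gene lengths must be positive")
  rate <- x$values / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero))
    stopf("sample(s) with all-zero counts: %s",
          paste(head(sample_ids(x)[zero], 5), collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expr_matrix(tpm, unit = "TPM", gene_lengths = x$gene_lengths)
}

#' Log-transform a TPM matrix
#'
#' @param x an [expr_matrix()] with unit `"TPM"`.
#' @param pseudocount added before taking log2; default 1.
#' @return An `expr_matrix` with unit `"log2TPM"`.
#' @export
log2_tpm <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "TPM") stopf("log2_tpm expects unit 'TPM', got '%s'", x$unit)
  expr_matrix(log2(x$values + pseudocount), unit = "log2TPM",
              gene_lengths = x$gene_lengths)
}

#' Remove additive batch effects
#'
#' Per gene, the least-squares batch coefficients (batch means, no other
#' covariates) are subtracted and the per-gene grand mean restored. With a
#' single batch the input is returned unchanged. The operation is
#' idempotent.
#'
#' @param x an [expr_matrix()] with unit `"log2TPM"`.
#' @param batch per-sample batch labels, named or in column order.
#' @return A batch-corrected `expr_matrix` (unit `"log2TPM"`).
#' @export
correct_batch <- function(x, batch) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "log2TPM")
    stopf("correct_batch expects unit 'log2TPM', got '%s'", x$unit)
  n <- ncol(x$values)
  if (!is.null(names(batch))) {
    missing <- setdiff(sample_ids(x), names(batch))
    if (length(missing))
      stopf("no batch label for sample(s): %s",
            paste(head(missing, 5), collapse = ", "))
    batch <- batch[sample_ids(x)]
  }
  if (length(batch) != n) stopf("batch must have one label per sample")
  if (anyNA(batch)) stopf("batch labels contain NA")
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(x)
  if (any(table(batch) < 2)) stopf("every batch needs at least 2 samples")
  v <- x$values
  grand <- rowMeans(v)
  for (lev in levels(batch)) {
    idx <- which(batch == lev)
    v[, idx] <- v[, idx] - rowMeans(v[, idx, drop = FALSE])
  }
  v <- v + grand
  expr_matrix(v, unit = "log2TPM", gene_lengths = x$gene_lengths)
}

#' Top variable genes
#'
#' Genes ranked by variance of log2(TPM + 1) across samples (values are
#' used as-is when the matrix is already on the log2 scale). Ties are
#' broken by gene id, lexicographically.
#'
#' @param x an [expr_matrix()] (unit `"TPM"` or `"log2TPM"`).
#' @param n number of genes to return (default 2000).
#' @return Character vector of `n` gene ids in decreasing-variance order.
#' @export
top_variable_genes <- function(x, n = 2000) {
  stopifnot(inherits(x, "expr_matrix"))
  if (n <= 0) stopf("n must be positive")
  if (n > nrow(x$values)) stopf("n (%d) exceeds number of genes (%d)", n, nrow(x$values))
  v <- if (x$unit == "log2TPM") x$values else log2(x$values + 1)
  vars <- apply(v, 1, var)
  ord <- c_order(-vars, rownames(v))
  rownames(v)[ord][seq_len(n)]
}

#' PCA embedding of samples
#'
#' Principal components of the per-gene-centered log2 expression matrix.
#' Sign convention: within each component the largest-magnitude gene
#' loading is made positive.
#'
#' @param x an [expr_matrix()].
#' @param k number of components, `k <= min(genes, samples)`.
#' @return List with `scores` (samples x k), `sdev` (component standard
#'   deviations) and `var_explained` (fractions).
#' @export
pca_embedding <- function(x, k) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- if (x$unit == "log2TPM") x$values else log2(x$values + 1)
  if (k < 1 || k > min(dim(v))) stopf("k must be in [1, min(genes, samples)]")
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  k_avail <- min(k, ncol(pc$x))
  flip <- vapply(seq_len(k_avail), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k_avail), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k_avail))
  list(scores = scores, sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
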