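#' Single-sample gene set enrichment (ssGSEA)
#'
#' Rank-weighted running-sum enrichment of one gene set in each sample.
#' Genes are ranked by decreasing expression within the sample (average
#' ranks for ties). Walking the ranked list, the in-set cumulative weight
#' P_in(i) (weights |rank|^tau) and the out-of-set cumulative count
#' P_out(i) are accumulated; the enrichment score is the sum of their
#' differences over all positions. With `normalize = TRUE` the scores for
#' each gene set are divided by their (max - min) range across the cohort.
#'
#' @param x an [expr_matrix()], or a genes x samples matrix, or a single
#'   named per-gene vector.
#' @param gene_sets a character vector (one set), a named list of
#'   character vectors, or a [signature_set()] (scored as `<name>_UP` and
#'   `<name>_DN`).
#' @param tau rank-weight exponent, >= 0 (default 0.25).
#' @param normalize divide each set's scores by their range across
#'   samples (default FALSE).
#' @return A sets x samples matrix of enrichment scores (dropped to a
#'   vector when a single set is given a plain vector input is scored).
#' @examples
#' expr <- matrix(c(4, 3, 2, 1), 4, 1,
#'                dimnames = list(paste0("g", 1:4), "s1"))
#' ssgsea(expr, list(top = "g1"), tau = 0)  # closed form: 2
#' @export
ssgsea <- function(x, gene_sets, tau = 0.25, normalize = FALSE) {
  if (tau < 0) stopf("tau must be >= 0")
  single_vec <- is.null(dim(x)) && !inherits(x, "expr_matrix")
  v <- if (single_vec) matrix(x, ncol = 1, dimnames = list(names(x), "sample")) else as_values(x)
  if (is.null(rownames(v))) stopf("expression values must carry gene ids")
  if (inherits(gene_sets, "signature_set")) {
    gene_sets <- setNames(list(gene_sets$up, gene_sets$down),
                          paste0(gene_sets$name, c("_UP", "_DN")))
  }
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  genes <- rownames(v)
  hits <- lapply(names(gene_sets), function(nm) {
    h <- genes %in% gene_sets[[nm]]
    if (!any(h)) stopf("gene set '%s' has no overlap with measured genes", nm)
    if (all(h)) stopf("gene set '%s' covers all measured genes", nm)
    h
  })
  names(hits) <- names(gene_sets)

  scores <- matrix(NA_real_, length(gene_sets), ncol(v),
                   dimnames = list(names(gene_sets), colnames(v)))
  for (s in seq_len(ncol(v))) {
    expr <- v[, s]
    r <- rank(expr, ties.method = "average")
    ord <- c_order(-r, genes)       # decreasing expression, stable ties
    w <- abs(r[ord])^tau
    for (j in seq_along(hits)) {
      h <- hits[[j]][ord]
      p_in <- cumsum(w * h) / sum(w * h)
      p_out <- cumsum(!h) / sum(!h)
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 1, function(z) diff(range(z)))
    rng[rng == 0] <- 1
    scores <- sweep(scores, 1, rng, "/")
  }
  if (single_vec && length(gene_sets) == 1) return(scores[1, 1])
  scores
}

#' Meningioma progression score (MPscore)
#'
#' Per-sample difference of ssGSEA enrichment for the progressive
#' subtype's up-regulated versus down-regulated signature genes:
#' `MPscore = ssGSEA(up) - ssGSEA(down)`. Given several signature sets,
#' the pairwise up-minus-down differences are summed.
#'
#' @param x an [expr_matrix()] or genes x samples matrix.
#' @param signature a [signature_set()] (or list of them) with non-empty
#'   up and down lists.
#' @param tau,normalize passed to [ssgsea()].
#' @return Named numeric vector of per-sample MPscores.
#' @export
mpscore <- function(x, signature, tau = 0.25, normalize = FALSE) {
  sigs <- if (inherits(signature, "signature_set")) list(signature) else signature
  v <- as_values(x)
  total <- setNames(numeric(ncol(v)), colnames(v))
  for (sig in sigs) {
    stopifnot(inherits(sig, "signature_set"))
    if (!length(sig$up) || !length(sig$down))
      stopf("signature '%s' needs non-empty up and down lists", sig$name)
    es <- ssgsea(v, setNames(list(sig$up, sig$down), c("up", "down")),
                 tau = tau, normalize = normalize)
    total <- total + es["up", ] - es["down", ]
  }
  total
}
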