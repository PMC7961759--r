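#' Moderated two-group differential expression
#'
#' Per-gene two-group linear model (one-vs-rest contrast) with
#' empirical-Bayes variance moderation: residual variances are shrunk
#' toward a pooled inverse-gamma prior fitted by the method of moments on
#' log s-squared (Smyth-style), giving a moderated t with augmented
#' degrees of freedom and two-sided p-values, plus Benjamini-Hochberg
#' adjusted p-values.
#'
#' Genes with zero residual variance in both groups get `p_value = 1`
#' (log fold change reported as computed) with a warning.
#'
#' @param x an [expr_matrix()] with unit `"log2TPM"`, or a plain matrix of
#'   log2 values (genes x samples).
#' @param groups per-sample labels (logical, factor or vector).
#' @param target the label identifying the group of interest; defaults to
#'   `TRUE` for logical `groups`, otherwise the first level. The log2
#'   fold change is mean(target) - mean(rest).
#' @param prior_df prior degrees of freedom: `NULL` (default) estimates
#'   d0 and s0^2 from the data; `0` gives the ordinary pooled t-test;
#'   `Inf` fully shrinks every variance to the prior mean.
#' @return A data.frame of class `deg_result` with columns `gene`,
#'   `logFC`, `ave_expr`, `t`, `df_total`, `p_value`, `adj_p`; the fitted
#'   prior is in attributes `prior_df` and `prior_s2`.
#' @export
moderated_de <- function(x, groups, target = NULL, prior_df = NULL) {
  v <- if (inherits(x, "expr_matrix")) {
    if (x$unit != "log2TPM")
      stopf("moderated_de expects log2-scale values (unit 'log2TPM')")
    x$values
  } else as.matrix(x)
  if (length(groups) != ncol(v)) stopf("groups must have one label per sample")
  if (is.null(target)) {
    target <- if (is.logical(groups)) TRUE else
      if (is.factor(groups)) levels(groups)[1] else unique(groups)[1]
  }
  in_g <- groups == target
  n1 <- sum(in_g); n2 <- sum(!in_g)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 samples on each side")

  m1 <- rowMeans(v[, in_g, drop = FALSE])
  m2 <- rowMeans(v[, !in_g, drop = FALSE])
  logfc <- m1 - m2
  ss1 <- rowSums((v[, in_g, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, !in_g, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  zero <- s2 == 0

  if (is.null(prior_df)) {
    fit <- fit_s2_prior(s2[!zero], df)
    d0 <- fit$df_prior; s02 <- fit$s2_prior
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2[!zero]) else NA_real_
  }

  if (d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- logfc / se
  df_total <- min(d0 + df, .Machine$double.xmax)
  p <- 2 * pt(-abs(tstat), df = df_total)
  if (any(zero)) {
    p[zero] <- 1
    tstat[zero & !is.finite(tstat)] <- NA_real_
    warnf("%d gene(s) with zero residual variance in both groups", sum(zero))
  }
  res <- data.frame(gene = rownames(v) %||% as.character(seq_len(nrow(v))),
                    logFC = logfc, ave_expr = rowMeans(v), t = tstat,
                    df_total = rep(df_total, length(tstat)),
                    p_value = p, adj_p = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "prior_df") <- d0
  attr(res, "prior_s2") <- s02
  class(res) <- c("deg_result", "data.frame")
  res
}

# Method-of-moments fit of the inverse-gamma variance prior on log s2
# (moments of log chi-square; Smyth 2004 style).
fit_s2_prior <- function(s2, df) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2) return(list(df_prior = 0, s2_prior = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # variances more concordant than chi-square sampling alone: infinite prior df
    return(list(df_prior = Inf, s2_prior = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, s2_prior = s02)
}

# Newton inversion of the trigamma function on (0, Inf).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; a validating wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene signature container
#'
#' Named up/down gene lists; the subtype-3 signature is the MPscore
#' reference.
#'
#' @param name signature name.
#' @param up,down character vectors of gene ids; must be disjoint.
#' @return Object of class `signature_set`.
#' @export
signature_set <- function(name, up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stopf("up and down lists must be disjoint")
  structure(list(name = name, up = up, down = down), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Extract an up/down signature from a differential-expression result
#'
#' Up-regulated: adjusted p strictly below `fdr` and log2 fold change
#' strictly above `lfc`; down-regulated: adjusted p strictly below `fdr`
#' and log2 fold change strictly below `-lfc`. Both lists are sorted by
#' adjusted p ascending.
#'
#' @param deg a [moderated_de()] result.
#' @param fdr adjusted-p threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 2).
#' @param name signature name (default `"signature"`).
#' @return A [signature_set()].
#' @export
extract_signature <- function(deg, fdr = 0.05, lfc = 2, name = "signature") {
  if (fdr <= 0 || lfc < 0) stopf("thresholds must be positive")
  ok <- !is.na(deg$adj_p) & deg$adj_p < fdr
  up <- deg[ok & deg$logFC > lfc, ]
  down <- deg[ok & deg$logFC < -lfc, ]
  if (nrow(up) == 0 && nrow(down) == 0)
    stopf("no signature at thresholds (fdr < %g, |log2FC| > %g)", fdr, lfc)
  signature_set(name,
                up = up$gene[order(up$adj_p, up$gene)],
                down = down$gene[order(down$adj_p, down$gene)])
}
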