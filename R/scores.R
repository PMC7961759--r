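#' Stemness index
#'
#' Per-sample Spearman correlation between a stem-cell-derived gene
#' weight vector and the sample's expression over the overlapping genes,
#' rescaled across the cohort to `[0, 1]` (min-max).
#'
#' @param x an [expr_matrix()] or genes x samples matrix.
#' @param weights named per-gene weights; at least 10 genes must overlap
#'   the matrix.
#' @return Named numeric vector of stemness indices in `[0, 1]`.
#' @export
stemness_index <- function(x, weights) {
  v <- as_values(x)
  common <- intersect(rownames(v), names(weights))
  if (length(common) < 10)
    stopf("need >= 10 overlapping genes between weights and matrix (got %d)",
          length(common))
  sub <- v[common, , drop = FALSE]
  w <- weights[common]
  zero_var <- apply(sub, 2, function(col) var(col) == 0)
  if (any(zero_var))
    stopf("zero-variance sample(s): %s",
          paste(head(colnames(sub)[zero_var], 5), collapse = ", "))
  raw <- apply(sub, 2, function(col) cor(w, col, method = "spearman"))
  rng <- range(raw)
  if (diff(rng) == 0) return(setNames(rep(0.5, length(raw)), colnames(sub)))
  setNames((raw - rng[1]) / diff(rng), colnames(sub))
}

#' Immune population scores
#'
#' Marker-aggregation abundance scores in the MCP-counter style: each
#' population's score in a sample is the arithmetic mean of the log2
#' expression of that population's marker genes.
#'
#' @param x an [expr_matrix()] with unit `"log2TPM"` (a `"TPM"` matrix is
#'   log2(TPM + 1)-transformed first), or a plain log2 matrix.
#' @param panels named list mapping population to marker gene ids (e.g.
#'   read from GMT via [read_gmt()], or `markers` of
#'   [default_immune_panels()] elements).
#' @return samples x populations matrix of scores (log2 units).
#' @export
immune_scores <- function(x, panels) {
  v <- if (inherits(x, "expr_matrix")) {
    if (x$unit == "log2TPM") x$values else log2(x$values + 1)
  } else as.matrix(x)
  if (!length(panels)) stopf("no panels given")
  panels <- lapply(panels, function(p) if (is.list(p)) p$markers else p)
  out <- vapply(names(panels), function(nm) {
    mk <- intersect(panels[[nm]], rownames(v))
    if (!length(mk)) stopf("panel '%s' has no measured markers", nm)
    colMeans(v[mk, , drop = FALSE])
  }, numeric(ncol(v)))
  rownames(out) <- colnames(v)
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney identity: AUC = U / (n_pos * n_neg), with tied scores
#' counted 0.5. No automatic direction flipping is applied; the caller
#' chooses the orientation of `scores`.
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   positive class is `TRUE`, `1`, or the second level).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  pos <- if (is.logical(labels)) labels
         else if (is.factor(labels)) labels == levels(labels)[2]
         else labels == max(labels)
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' @param values per-sample numeric values.
#' @param groups group labels (>= 2 groups, >= 2 samples each).
#' @return List with `f` (ANOVA F), `p_value`, and `tukey` (data.frame of
#'   pairwise comparisons: `pair`, `diff`, `lwr`, `upr`, `p_adj`). With
#'   all values identical, `f = 0` and `p_value = 1` by convention.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 samples")
  if (var(values) == 0) {
    # all values identical: no between- or within-group variation
    pairs <- utils::combn(levels(groups), 2)
    tukey <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                        diff = 0, lwr = 0, upr = 0, p_adj = 1)
    return(list(f = 0, p_value = 1, tukey = tukey))
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tk <- suppressWarnings(TukeyHSD(fit)$groups)
  if (!is.finite(f)) {
    # zero between- and within-group variance: no evidence of differences
    f <- 0; p <- 1
    tk[, "p adj"] <- 1
    tk[!is.finite(tk[, "lwr"]), c("lwr", "upr")] <- 0
  }
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(f = f, p_value = p, tukey = tukey)
}

#' Random-forest marker ranking with recursive elimination
#'
#' One-vs-rest random-forest classification of a target subtype.
#' Importance is the permutation-based mean decrease in accuracy from a
#' forest on all genes; the cross-validated error curve is computed by
#' recursive feature elimination (retained-variable count divided by
#' `step` per round) with `cv_folds`-fold cross-validation
#' (`randomForest::rfcv`).
#'
#' @param x an [expr_matrix()] (log2 scale recommended) or matrix.
#' @param labels per-sample subtype labels.
#' @param target the subtype contrasted against the rest.
#' @param n_trees trees per forest (default 500).
#' @param cv_folds cross-validation folds (default 10).
#' @param step variable-count reduction factor per elimination round
#'   (default 1.5; must be > 1).
#' @param cv run the cross-validated elimination (default TRUE; the
#'   importance ranking alone is much cheaper).
#' @param seed RNG seed.
#' @return Object of class `marker_ranking`: `importance` (data.frame
#'   gene, importance, rank) and `cv_error` (data.frame n_var, error; NULL
#'   when `cv = FALSE`).
#' @export
rf_marker_ranking <- function(x, labels, target, n_trees = 500,
                              cv_folds = 10, step = 1.5, cv = TRUE,
                              seed = 1) {
  if (step <= 1) stopf("step must be > 1")
  v <- as_values(x)
  if (length(labels) != ncol(v)) stopf("labels must have one entry per sample")
  y <- factor(ifelse(labels == target, "target", "rest"), levels = c("rest", "target"))
  if (min(table(y)) < 5) stopf("need >= 5 samples per class")
  X <- t(v)
  with_seed(seed, {
    rf <- randomForest::randomForest(X, y, ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    ord <- c_order(-imp, names(imp))
    importance <- data.frame(gene = names(imp)[ord], importance = imp[ord],
                             rank = seq_along(imp), row.names = NULL)
    cv_error <- NULL
    if (cv) {
      cvres <- randomForest::rfcv(X, y, cv.fold = cv_folds, scale = "log",
                                  step = 1 / step, ntree = n_trees)
      cv_error <- data.frame(n_var = as.integer(names(cvres$error.cv)),
                             error = unname(cvres$error.cv))
    }
  })
  structure(list(importance = importance, cv_error = cv_error,
                 target = target), class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, ...) {
  cat(sprintf("<marker_ranking> target = %s; top genes: %s\n", x$target,
              paste(head(x$importance$gene, 5), collapse = ", ")))
  if (!is.null(x$cv_error)) {
    best <- x$cv_error[which.min(x$cv_error$error), ]
    cat(sprintf("  min CV error %.3f at %d variables\n", best$error, best$n_var))
  }
  invisible(x)
}
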