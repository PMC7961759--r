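#' Beta to M values
#'
#' M = log2(beta / (1 - beta)) after clipping beta to
#' `[eps, 1 - eps]` so the transform stays finite. M values are used for
#' statistical testing; beta values for biological interpretation.
#'
#' @param beta CpG x samples matrix of beta values in `[0, 1]`.
#' @param eps clipping bound (default 1e-6).
#' @return Matrix of M values, same dimensions.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stopf("beta values must be in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' CpG island methylator phenotype (CIMP) call
#'
#' Per group, the variable loci are those whose within-group beta
#' standard deviation exceeds `sd_threshold`; the group is CIMP-positive
#' when more than half of its variable loci have group-mean beta above
#' `hyper_beta`.
#'
#' @param beta CpG x samples beta matrix.
#' @param groups per-sample group labels (>= 3 samples per group).
#' @param sd_threshold within-group SD defining a variable locus
#'   (default 0.2).
#' @param hyper_beta group-mean beta defining hypermethylation
#'   (default 0.5).
#' @return Named logical vector, one CIMP flag per group (`NA` with a
#'   warning when a group has no variable loci).
#' @export
call_cimp <- function(beta, groups, sd_threshold = 0.2, hyper_beta = 0.5) {
  beta <- as.matrix(beta)
  if (length(groups) != ncol(beta)) stopf("groups must have one label per sample")
  groups <- factor(groups)
  if (any(table(groups) < 3)) stopf("every group needs >= 3 samples")
  out <- setNames(rep(NA, nlevels(groups)), levels(groups))
  for (g in levels(groups)) {
    sub <- beta[, groups == g, drop = FALSE]
    sds <- apply(sub, 1, sd)
    variable <- sds > sd_threshold
    if (!any(variable)) {
      warnf("group '%s' has no variable loci; CIMP flag undefined", g)
      next
    }
    means <- rowMeans(sub[variable, , drop = FALSE])
    out[g] <- mean(means > hyper_beta) > 0.5
  }
  out
}

#' Subtype-specific differentially methylated CpG signatures
#'
#' Moderated differential testing ([moderated_de()]) on M values in a
#' pairwise fashion between groups. A locus belongs to a group's
#' signature when it is significant (|delta M| > `lfc`, BH-adjusted
#' p < `fdr`) in every pairwise contrast involving that group.
#'
#' @param beta CpG x samples beta matrix.
#' @param groups per-sample group labels (>= 2 per group).
#' @param lfc |delta M| threshold (default 2).
#' @param fdr adjusted-p threshold (default 0.05).
#' @return Named list, one element per group: data.frame with `cpg_id`
#'   and `direction` (sign of the mean delta M across contrasts).
#' @export
dm_signature <- function(beta, groups, lfc = 2, fdr = 0.05) {
  m <- beta_to_m(beta)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  levs <- levels(groups)
  out <- list()
  for (g in levs) {
    others <- setdiff(levs, g)
    keep <- rep(TRUE, nrow(m))
    dm_sum <- numeric(nrow(m))
    for (h in others) {
      sel <- groups %in% c(g, h)
      deg <- moderated_de(m[, sel, drop = FALSE], groups[sel], target = g)
      keep <- keep & !is.na(deg$adj_p) & deg$adj_p < fdr & abs(deg$logFC) > lfc
      dm_sum <- dm_sum + deg$logFC
    }
    ids <- rownames(m)[keep]
    out[[g]] <- data.frame(cpg_id = ids,
                           direction = sign(dm_sum[keep]),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Call arm-level copy-number loss
#'
#' A sample has lost an arm when its mean copy-number value for that arm
#' is strictly below `threshold`.
#'
#' @param cn samples x arms matrix or data.frame of arm-level mean
#'   copy-number values.
#' @param arm arm name (e.g. `"chr1p"`, `"chr22q"`).
#' @param threshold loss threshold (default 0.1, strict `<`).
#' @return Named logical vector, one call per sample.
#' @export
call_arm_loss <- function(cn, arm, threshold = 0.1) {
  cn <- as.matrix(cn)
  if (!arm %in% colnames(cn)) stopf("arm '%s' not present", arm)
  vals <- cn[, arm]
  setNames(vals < threshold, rownames(cn))
}

#' Rule-based methylation subtype assignment
#'
#' Sequential decision rules for a methylation-only cohort:
#' \enumerate{
#'   \item chr1p loss AND chr22q loss: subtype 3
#'   \item chr22q loss alone: subtype 2
#'   \item stemness index above `si_threshold`: subtype 4
#'   \item neither chr1p nor chr22q loss: subtype 1
#' }
#' Samples matching no rule (chr1p loss alone with low SI) stay
#' unassigned (`NA`) with a warning.
#'
#' @param loss_1p,loss_22q logical arm-loss calls per sample (see
#'   [call_arm_loss()]).
#' @param si stemness index in `[0, 1]` per sample.
#' @param si_threshold SI cut for subtype 4 (default 0.5, strict `>`).
#' @return Integer vector of subtype labels in `{1, 2, 3, 4}` (or `NA`).
#' @export
assign_methylation_subtype <- function(loss_1p, loss_22q, si,
                                       si_threshold = 0.5) {
  n <- length(si)
  if (length(loss_1p) != n || length(loss_22q) != n)
    stopf("loss_1p, loss_22q and si must have equal length")
  if (anyNA(loss_1p) || anyNA(loss_22q) || anyNA(si))
    stopf("missing inputs: arm calls and SI must be complete")
  if (any(si < 0 | si > 1)) stopf("si must be in [0, 1]")
  out <- rep(NA_integer_, n)
  out[loss_1p & loss_22q] <- 3L
  rest <- is.na(out) & loss_22q
  out[rest] <- 2L
  rest <- is.na(out) & si > si_threshold
  out[rest] <- 4L
  rest <- is.na(out) & !loss_1p & !loss_22q
  out[rest] <- 1L
  if (anyNA(out))
    warnf("%d sample(s) match no assignment rule (chr1p loss alone, low SI)",
          sum(is.na(out)))
  names(out) <- names(si)
  out
}
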