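#' Kaplan-Meier estimate per group
#'
#' Product-limit survival estimates with right censoring, via
#' `survival::survfit`.
#'
#' @param time follow-up times (> 0, months).
#' @param event event indicators (0/1 or logical).
#' @param group optional group labels; default one group.
#' @return data.frame of class `km_estimate`: `group`, `time`, `n_risk`,
#'   `n_event`, `surv` (S(0) = 1 rows included).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stopf("times must be positive")
  event <- as.integer(event)
  if (is.null(group)) group <- rep("all", length(time))
  if (length(group) != length(time)) stopf("group must match time in length")
  df <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(df$group)[1], length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  out <- data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, surv = sm$surv,
                    stringsAsFactors = FALSE)
  zero <- data.frame(group = unique(strata), time = 0,
                     n_risk = as.vector(table(df$group)[unique(strata)]),
                     n_event = 0, surv = 1, stringsAsFactors = FALSE)
  out <- rbind(zero, out)
  out <- out[order(out$group, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic (1 df) via
#' `survival::survdiff`.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-group labels.
#' @return List with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time <= 0)) stopf("times must be positive")
  group <- factor(group)
  if (nlevels(group) != 2) stopf("logrank_test expects exactly 2 groups")
  if (any(table(group) == 0)) stopf("a group is empty")
  event <- as.integer(event)
  if (sum(event) == 0) stopf("no events observed")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd$chisq
  list(chisq = chisq, df = 1,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Breslow tie handling by default)
#' via `survival::coxph`, with Wald confidence intervals and p-values.
#' Categorical covariates are dummy-coded against their first level.
#' Constant covariates are rejected with an error naming them.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame of class `cox_fit`: `term`, `coef` (log hazard
#'   ratio), `hr`, `se`, `lower95`, `upper95` (hazard-ratio scale),
#'   `lower95_log`, `upper95_log` (log scale), `p_value`.
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  if (any(data$time <= 0)) stopf("times must be positive")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stopf("covariate(s) not in data: %s", paste(missing_cov, collapse = ", "))
  for (cv in covariates) {
    vals <- data[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2)
      stopf("covariate '%s' is constant across samples", cv)
  }
  n_events <- sum(data$event)
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = data, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w)))
        stopf("Cox fit failed: %s", conditionMessage(w))
      suppressWarnings(survival::coxph(form, data = data, ties = ties,
                                       control = survival::coxph.control(iter.max = 100)))
    })
  if (n_events < length(coef(fit)) + 1)
    stopf("too few events (%d) for %d coefficients", n_events, length(coef(fit)))
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = co[, "exp(coef)"], se = co[, "se(coef)"],
                    lower95 = ci[, "lower .95"], upper95 = ci[, "upper .95"],
                    lower95_log = co[, "coef"] - qnorm(0.975) * co[, "se(coef)"],
                    upper95_log = co[, "coef"] + qnorm(0.975) * co[, "se(coef)"],
                    p_value = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cox_fit", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Median split of MPscores into high/low groups
#'
#' Samples strictly above the cohort median are "high"; ties at the
#' median go to "low". The cutpoint is recorded as an attribute.
#'
#' @param scores numeric MPscores (>= 2 samples, not all identical).
#' @return Factor with levels `low`, `high`; attribute `cutpoint`.
#' @export
dichotomize_mpscore <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 samples")
  if (length(unique(scores)) < 2) stopf("all scores identical; cannot dichotomize")
  cut <- median(scores)
  lab <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  names(lab) <- names(scores)
  attr(lab, "cutpoint") <- cut
  lab
}
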