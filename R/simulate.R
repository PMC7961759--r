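#' Default immune marker panels for the synthetic cohort
#'
#' Eight immune cell populations (the marker-aggregation design of
#' MCP-counter-style scoring), each with a small synthetic marker gene
#' panel and per-subtype log2 abundance shifts. Shift magnitudes are
#' specified at the reference planted effect size (log2 fold change 2) and
#' are scaled proportionally by `effect_log2fc / 2` inside
#' [simulate_cohort()]. The defaults encode: cytotoxic lymphocytes highest
#' in subtype 3, NK cells in subtype 4, neutrophils in subtype 1, and a
#' monocytic lineage depleted only in subtype 1.
#'
#' @param n_markers markers per population (default 5).
#' @return Named list; each element has `markers` (gene ids) and
#'   `log2_shift` (length-4 numeric, one shift per subtype).
#' @export
default_immune_panels <- function(n_markers = 5) {
  pops <- list(
    T_cells               = c(0.5, 0.5, 1.0, 0.5),
    CD8_T_cells           = c(0.0, 0.0, 1.5, 0.0),
    Cytotoxic_lymphocytes = c(0.0, 0.0, 1.5, 0.0),
    NK_cells              = c(0.0, 0.0, 0.0, 1.5),
    B_lineage             = c(0.0, 0.5, 0.5, 0.5),
    Monocytic_lineage     = c(0.0, 1.0, 1.0, 1.0),
    Myeloid_dendritic     = c(0.0, 0.5, 0.5, 0.5),
    Neutrophils           = c(1.0, 0.0, 0.0, 0.0)
  )
  out <- lapply(names(pops), function(p) {
    list(markers = sprintf("IMM_%s_%02d", toupper(p), seq_len(n_markers)),
         log2_shift = pops[[p]])
  })
  names(out) <- names(pops)
  out
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic meningioma cohort generator. The defaults
#' are the study conditions the package is tested under: 179 samples in
#' four subtypes (67/38/59/15, the WHO-grade column sums of the study's
#' cohort table), grade composition concentrated in the progressive
#' subtype 3, a planted 53-gene subtype-3 signature (20 up, 33 down) plus
#' per-subtype expression programs totalling 263 differential genes, two
#' batches, chr1p/chr22q losses in subtypes 2 and 3, subtype-3 CpG
#' hypermethylation, and a recurrence hazard ratio of 3 for subtype 3.
#'
#' @param n_per_subtype integer(4), samples per subtype.
#' @param n_genes total number of genes.
#' @param n_signature_up,n_signature_down planted subtype-3 up/down
#'   signature gene counts.
#' @param n_program_other planted program gene counts for subtypes 1, 2, 4
#'   (half shifted up, half down in that subtype).
#' @param effect_log2fc planted |log2 fold change| of signature and
#'   program genes; all other planted expression shifts scale by
#'   `effect_log2fc / 2`.
#' @param n_batches,batch_sd number of batches and per-gene batch shift SD
#'   (log2 units); batch 1 is the reference.
#' @param immune_panels marker panels, see [default_immune_panels()].
#' @param n_stemness,stemness_shift stemness program size and per-subtype
#'   log2 shifts (at the reference effect size).
#' @param hazard_ratio_progressive multiplicative recurrence hazard for
#'   subtype 3.
#' @param baseline_hazard events per month for non-progressive subtypes
#'   (default log(2)/60: median 60 months).
#' @param censor_rate target censoring fraction in the baseline group.
#' @param cpg_spec list: `n_cpg` loci, `n_variable` high-variance loci,
#'   `shift` subtype-3 hypermethylation shift (beta units).
#' @param arm_spec arms x subtypes matrix of mean copy-number values
#'   (copy-ratio-like: neutral about 1, loss well below the 0.1 calling
#'   threshold).
#' @param mean_log2,sd_log2,noise_sd baseline expression model: per-gene
#'   log2 means Normal(mean_log2, sd_log2), per-sample noise
#'   Normal(0, noise_sd).
#' @param seed RNG seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_subtype = c(67L, 38L, 59L, 15L),
                        n_genes = 3000,
                        n_signature_up = 20,
                        n_signature_down = 33,
                        n_program_other = c(80, 60, 70),
                        effect_log2fc = 2,
                        n_batches = 2,
                        batch_sd = 1,
                        immune_panels = default_immune_panels(),
                        n_stemness = 100,
                        stemness_shift = c(0, 0, 1, 2),
                        hazard_ratio_progressive = 3,
                        baseline_hazard = log(2) / 60,
                        censor_rate = 0.2,
                        cpg_spec = list(n_cpg = 2000, n_variable = 300, shift = 0.3),
                        arm_spec = NULL,
                        mean_log2 = 4, sd_log2 = 2, noise_sd = 0.5,
                        seed = 101) {
  if (is.null(arm_spec)) {
    arm_spec <- rbind(
      chr1p  = c(1, 1, -0.3, 1),
      chr22q = c(1, -0.3, -0.3, 1),
      chr7p  = c(1, 1, 1, 1),
      chr10q = c(1, 1, 1, 1)
    )
    colnames(arm_spec) <- paste0("subtype", 1:4)
  }
  spec <- list(
    n_per_subtype = as.integer(n_per_subtype), n_genes = as.integer(n_genes),
    n_signature_up = as.integer(n_signature_up),
    n_signature_down = as.integer(n_signature_down),
    n_program_other = as.integer(n_program_other),
    effect_log2fc = effect_log2fc, n_batches = as.integer(n_batches),
    batch_sd = batch_sd, immune_panels = immune_panels,
    n_stemness = as.integer(n_stemness), stemness_shift = stemness_shift,
    hazard_ratio_progressive = hazard_ratio_progressive,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    cpg_spec = cpg_spec, arm_spec = arm_spec,
    mean_log2 = mean_log2, sd_log2 = sd_log2, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  if (length(s$n_per_subtype) != 4 || any(s$n_per_subtype <= 0))
    stopf("n_per_subtype must be 4 positive integers")
  if (s$n_genes <= 0) stopf("n_genes must be positive")
  if (s$n_signature_up <= 0 || s$n_signature_down <= 0)
    stopf("signature gene counts must be positive")
  if (length(s$n_program_other) != 3 || any(s$n_program_other < 0))
    stopf("n_program_other must be 3 non-negative counts (subtypes 1, 2, 4)")
  if (s$effect_log2fc < 0) stopf("effect_log2fc must be >= 0")
  if (s$batch_sd < 0) stopf("batch_sd must be >= 0")
  if (s$n_batches < 1) stopf("n_batches must be >= 1")
  if (s$censor_rate < 0 || s$censor_rate > 1) stopf("censor_rate must be in [0, 1]")
  if (s$hazard_ratio_progressive <= 0) stopf("hazard_ratio_progressive must be > 0")
  if (s$cpg_spec$n_variable > s$cpg_spec$n_cpg)
    stopf("cpg_spec$n_variable exceeds n_cpg")
  if (s$cpg_spec$shift < 0 || s$cpg_spec$shift > 1)
    stopf("cpg_spec$shift must keep beta values clippable to [0, 1]")
  n_markers <- sum(vapply(s$immune_panels, function(p) length(p$markers), numeric(1)))
  planted <- s$n_signature_up + s$n_signature_down + sum(s$n_program_other) +
    n_markers + s$n_stemness
  if (s$n_genes < planted)
    stopf("n_genes (%d) is smaller than the %d planted genes (signature + programs + markers + stemness)",
          s$n_genes, planted)
  invisible(s)
}

# Grade composition per subtype (WHO rows of the study's cohort table).
grade_table <- function() {
  m <- rbind(I = c(67, 32, 28, 13), II = c(0, 6, 24, 2), III = c(0, 0, 7, 0))
  colnames(m) <- paste0("subtype", 1:4)
  m
}

#' Simulate a synthetic meningioma cohort
#'
#' Generates a cohort carrying every statistical structure the downstream
#' pipeline stages assume: a TPM expression matrix on a log-normal
#' baseline with planted per-subtype differential programs (the subtype-3
#' program is the up/down signature used as the MPscore reference),
#' additive per-gene batch shifts, immune marker structure, a stemness
#' program plus matching weight vector, CpG beta values with subtype-3
#' hypermethylation, arm-level copy-number means with chr1p/chr22q losses,
#' and exponential recurrence times with an increased hazard for
#' subtype 3. Deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   ([expr_matrix()], unit TPM), `annotations` (sample_id, subtype,
#'   grade, batch, sex), `survival` (sample_id, time, event, mib1,
#'   location, sex), `methylation` (`beta` matrix and `cpg_annotations`),
#'   `arm_cn` (samples x arms), `stemness_weights`, `truth` (planted
#'   parameters; see [truth_report()]), and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n_sub <- spec$n_per_subtype
  n <- sum(n_sub)
  subtype <- rep(1:4, times = n_sub)
  sample_id <- sprintf("S%03d", seq_len(n))

  ## --- gene identities -------------------------------------------------
  sig_up <- sprintf("SIG3_UP_%02d", seq_len(spec$n_signature_up))
  sig_dn <- sprintf("SIG3_DN_%02d", seq_len(spec$n_signature_down))
  prg <- list()
  for (i in seq_along(c(1, 2, 4))) {
    st <- c(1, 2, 4)[i]
    k <- spec$n_program_other[i]
    prg[[paste0("subtype", st)]] <- if (k > 0) sprintf("PRG%d_%03d", st, seq_len(k)) else character(0)
  }
  imm_genes <- unlist(lapply(spec$immune_panels, `[[`, "markers"), use.names = FALSE)
  stem_genes <- if (spec$n_stemness > 0) sprintf("STEM_%03d", seq_len(spec$n_stemness)) else character(0)
  planted <- c(sig_up, sig_dn, unlist(prg, use.names = FALSE), imm_genes, stem_genes)
  filler <- sprintf("G%05d", seq_len(spec$n_genes - length(planted)))
  genes <- c(planted, filler)

  ## --- per-sample labels ----------------------------------------------
  gt <- grade_table()
  grade <- unlist(lapply(1:4, function(st) {
    sample(rownames(gt), n_sub[st], replace = TRUE, prob = gt[, st])
  }))
  batch <- sample(seq_len(spec$n_batches), n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(107, 57) / 164)

  ## --- expression (log2 scale, then TPM) -------------------------------
  scale_eff <- spec$effect_log2fc / 2   # reference effect size is 2
  mu <- rnorm(spec$n_genes, spec$mean_log2, spec$sd_log2)
  names(mu) <- genes
  shift <- matrix(0, spec$n_genes, 4, dimnames = list(genes, paste0("subtype", 1:4)))
  shift[sig_up, 3] <- spec$effect_log2fc
  shift[sig_dn, 3] <- -spec$effect_log2fc
  for (st in c(1, 2, 4)) {
    g <- prg[[paste0("subtype", st)]]
    if (length(g)) {
      half <- ceiling(length(g) / 2)
      shift[g[seq_len(half)], st] <- spec$effect_log2fc
      shift[g[-seq_len(half)], st] <- -spec$effect_log2fc
    }
  }
  for (p in spec$immune_panels)
    shift[p$markers, ] <- shift[p$markers, ] +
      matrix(p$log2_shift * scale_eff, length(p$markers), 4, byrow = TRUE)
  if (length(stem_genes))
    shift[stem_genes, ] <- shift[stem_genes, ] +
      matrix(spec$stemness_shift * scale_eff, length(stem_genes), 4, byrow = TRUE)

  batch_delta <- matrix(0, spec$n_genes, spec$n_batches)
  if (spec$n_batches > 1 && spec$batch_sd > 0)
    batch_delta[, -1] <- rnorm(spec$n_genes * (spec$n_batches - 1), 0, spec$batch_sd)

  x <- mu + shift[, subtype] + batch_delta[, batch] +
    matrix(rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
  tpm <- 2^x
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(genes, sample_id)

  ## --- stemness weight vector ------------------------------------------
  w_extra <- sample(filler, min(400, length(filler)))
  weights <- c(rnorm(length(stem_genes), 3, 0.3), rnorm(length(w_extra), 0, 1))
  names(weights) <- c(stem_genes, w_extra)

  ## --- survival ---------------------------------------------------------
  rate <- spec$baseline_hazard * ifelse(subtype == 3, spec$hazard_ratio_progressive, 1)
  t_event <- rexp(n, rate)
  if (spec$censor_rate > 0) {
    c_rate <- spec$baseline_hazard * spec$censor_rate / (1 - spec$censor_rate)
    t_cens <- rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  mib1 <- pmax(0.1, rnorm(n, 3 + 3 * (subtype == 3), 1.5))
  locations <- c("Skull base", "Convexity", "Falx", "Intraventricular",
                 "Olfactory groove", "Optic nerve", "Parasagittal",
                 "Posterior fossa", "Sphenoid wing", "Suprasellar")
  location <- sample(locations, n, replace = TRUE)

  ## --- methylation ------------------------------------------------------
  cs <- spec$cpg_spec
  cpg_id <- sprintf("cg%07d", seq_len(cs$n_cpg))
  variable <- seq_len(cs$n_variable)
  state_mean <- ifelse(runif(cs$n_cpg) < 0.6, 0.15, 0.85)
  conc <- 40
  beta <- matrix(rbeta(cs$n_cpg * n, state_mean * conc, (1 - state_mean) * conc),
                 cs$n_cpg, n)
  if (cs$n_variable > 0) {
    # high-variance loci: mean 0.3, sd 0.25 (Beta(0.708, 1.652))
    beta[variable, ] <- rbeta(cs$n_variable * n, 0.708, 1.652)
    beta[variable, subtype == 3] <- beta[variable, subtype == 3] + cs$shift
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(cpg_id, sample_id)
  is_var <- seq_len(cs$n_cpg) %in% variable
  cpg_ann <- data.frame(
    cpg_id = cpg_id,
    island = runif(cs$n_cpg) < ifelse(is_var, 0.9, 0.3),
    promoter = runif(cs$n_cpg) < ifelse(is_var, 0.9, 0.4),
    arm = sample(rownames(spec$arm_spec), cs$n_cpg, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## --- arm-level copy number -------------------------------------------
  arms <- rownames(spec$arm_spec)
  arm_cn <- vapply(arms, function(a) {
    rnorm(n, spec$arm_spec[a, subtype], 0.1)
  }, numeric(n))
  rownames(arm_cn) <- sample_id

  annotations <- data.frame(sample_id = sample_id, subtype = subtype,
                            grade = grade, batch = batch, sex = sex,
                            stringsAsFactors = FALSE)
  survival <- data.frame(sample_id = sample_id, time = time, event = event,
                         mib1 = mib1, location = location, sex = sex,
                         stringsAsFactors = FALSE)
  truth <- list(
    subtype = setNames(subtype, sample_id),
    signature_up = sig_up, signature_down = sig_dn,
    program = prg, immune_panels = spec$immune_panels,
    stemness_genes = stem_genes,
    effect_log2fc = spec$effect_log2fc,
    hazard_ratio_progressive = spec$hazard_ratio_progressive,
    shift = shift,
    variable_cpg = cpg_id[variable],
    cpg_shift = cs$shift,
    arm_spec = spec$arm_spec,
    batch = setNames(batch, sample_id)
  )
  structure(list(expression = expr_matrix(tpm, unit = "TPM"),
                 annotations = annotations, survival = survival,
                 methylation = list(beta = beta, cpg_annotations = cpg_ann),
                 arm_cn = arm_cn, stemness_weights = weights,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%s per subtype), %d genes, %d CpG loci\n",
              ncol(x$expression$values),
              paste(x$spec$n_per_subtype, collapse = "/"),
              nrow(x$expression$values), nrow(x$methylation$beta)))
  invisible(x)
}

#' Report the planted truth of a synthetic cohort
#'
#' Read-only view of the planted parameters (labels, signature genes,
#' effect sizes, hazard ratio, hypermethylated loci) for recovery tests.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return The cohort's `truth` list.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}
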