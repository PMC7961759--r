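#' Pipeline configuration
#'
#' Builds the full stage-parameter configuration with defaults mirroring
#' every operation's defaults. Unknown keys are rejected. The
#' configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param cohort named list of [cohort_spec()] arguments (the generator
#'   seed is derived from the global `seed`).
#' @param preprocess list: `pseudocount`, `top_n`.
#' @param cluster list: `k_min`, `k_max`, `n_resamples`, `sample_frac`,
#'   `delta_threshold`, `sigclust_n_sim`.
#' @param signature list: `fdr`, `lfc`.
#' @param score list: `tau`, `normalize`.
#' @param methyl list: `sd_threshold`, `hyper_beta`, `arm_threshold`,
#'   `si_threshold`.
#' @param survival list: `cutpoint` (only `"median"`), `ties`.
#' @param seed global seed; per-stage seeds are derived deterministically
#'   from it and the stage name.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), preprocess = list(),
                            cluster = list(), signature = list(),
                            score = list(), methyl = list(),
                            survival = list(), seed = 1) {
  defaults <- list(
    cohort = list(
      n_per_subtype = c(67L, 38L, 59L, 15L), n_genes = 3000L,
      n_signature_up = 20L, n_signature_down = 33L,
      n_program_other = c(80L, 60L, 70L), effect_log2fc = 2,
      n_batches = 2L, batch_sd = 1, n_stemness = 100L,
      stemness_shift = c(0, 0, 1, 2), hazard_ratio_progressive = 3,
      baseline_hazard = log(2) / 60, censor_rate = 0.2,
      cpg_spec = list(n_cpg = 2000L, n_variable = 300L, shift = 0.3)
    ),
    preprocess = list(pseudocount = 1, top_n = 2000L),
    cluster = list(k_min = 2L, k_max = 6L, n_resamples = 1000L,
                   sample_frac = 0.8, delta_threshold = 0.025,
                   sigclust_n_sim = 100L),
    signature = list(fdr = 0.05, lfc = 2),
    score = list(tau = 0.25, normalize = FALSE),
    methyl = list(sd_threshold = 0.2, hyper_beta = 0.5,
                  arm_threshold = 0.1, si_threshold = 0.5),
    survival = list(cutpoint = "median", ties = "breslow")
  )
  user <- list(cohort = cohort, preprocess = preprocess, cluster = cluster,
               signature = signature, score = score, methyl = methyl,
               survival = survival)
  cfg <- defaults
  for (section in names(user)) {
    extra <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(extra))
      stopf("unknown key(s) in config section '%s': %s", section,
            paste(extra, collapse = ", "))
    cfg[[section]][names(user[[section]])] <- user[[section]]
  }
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  n_samples <- sum(cfg$cohort$n_per_subtype)
  if (cfg$cluster$k_max >= n_samples)
    stopf("k_max (%d) must be smaller than the number of samples (%d)",
          cfg$cluster$k_max, n_samples)
  if (cfg$cluster$k_min < 2) stopf("k_min must be >= 2")
  if (cfg$preprocess$top_n > cfg$cohort$n_genes)
    stopf("top_n (%d) exceeds n_genes (%d)", cfg$preprocess$top_n, cfg$cohort$n_genes)
  invisible(cfg)
}

#' Write / read a pipeline configuration (YAML)
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1
  raw$seed <- NULL
  known <- c("cohort", "preprocess", "cluster", "signature", "score",
             "methyl", "survival")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stopf("unknown config section(s): %s", paste(extra, collapse = ", "))
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

pipeline_stages <- c("simulate", "preprocess", "cluster", "signature",
                     "score", "methyl", "survival")

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> cluster -> signature -> score ->
#' methyl -> survival. Each stage reads its inputs from the run directory,
#' writes versioned text outputs into `<outdir>/<stage>/`, and updates a
#' JSON manifest (parameters, derived seed, output checksums, wall time).
#' Reruns with the same config and seed are bit-identical for
#' deterministic stages. A stage failure aborts with the failing stage
#' named; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @param stages which stages to run (`"all"` or a subset of
#'   `simulate, preprocess, cluster, signature, score, methyl, survival`;
#'   prerequisite outputs must already exist in `outdir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  else list(package_version = as.character(packageVersion("mprog")),
            seed = config$seed, stages = list())

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    seed <- derive_seed(config$seed, stage)
    dir.create(file.path(outdir, stage), showWarnings = FALSE)
    result <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, outdir, seed),
             preprocess = stage_preprocess(config, outdir, seed),
             cluster = stage_cluster(config, outdir, seed),
             signature = stage_signature(config, outdir, seed),
             score = stage_score(config, outdir, seed),
             methyl = stage_methyl(config, outdir, seed),
             survival = stage_survival(config, outdir, seed)),
      error = function(e) {
        stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
      })
    files <- list.files(file.path(outdir, stage), full.names = TRUE)
    sums <- as.list(tools::md5sum(files))
    names(sums) <- basename(files)
    manifest$stages[[stage]] <- list(
      status = "complete", seed = seed,
      params = config[[if (stage == "simulate") "cohort" else stage]] %||% list(),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = sums)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

stage_dir <- function(outdir, stage) file.path(outdir, stage)

need_file <- function(outdir, stage, file) {
  p <- file.path(outdir, stage, file)
  if (!file.exists(p))
    stopf("missing input %s (run stage '%s' first)", p, stage)
  p
}

stage_simulate <- function(config, outdir, seed) {
  args <- config$cohort
  args$seed <- seed
  cohort <- simulate_cohort(do.call(cohort_spec, args))
  d <- stage_dir(outdir, "simulate")
  write_gct(cohort$expression, file.path(d, "expression.gct"))
  write_matrix_tsv(cohort$expression$values, file.path(d, "expression.tsv"), "gene_id")
  write_df_csv(cohort$annotations, file.path(d, "annotations.csv"))
  write_df_csv(cohort$survival, file.path(d, "survival.csv"))
  write_matrix_tsv(cohort$methylation$beta, file.path(d, "beta.tsv"), "cpg_id")
  write_df_csv(cohort$methylation$cpg_annotations, file.path(d, "cpg_annotations.csv"))
  write_matrix_tsv(cohort$arm_cn, file.path(d, "arms.tsv"), "sample_id")
  write_gmt(cohort$truth$immune_panels, file.path(d, "panels.gmt"))
  write_df_csv(data.frame(gene_id = names(cohort$stemness_weights),
                          weight = unname(cohort$stemness_weights)),
               file.path(d, "stemness_weights.csv"))
  jsonlite::write_json(cohort$truth[c("signature_up", "signature_down",
                                      "effect_log2fc",
                                      "hazard_ratio_progressive",
                                      "variable_cpg")],
                       file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_df_csv(data.frame(sample_id = names(cohort$truth$subtype),
                          subtype = unname(cohort$truth$subtype)),
               file.path(d, "truth_subtypes.csv"))
  invisible(TRUE)
}

stage_preprocess <- function(config, outdir, seed) {
  expr <- expr_matrix(read_matrix_tsv(need_file(outdir, "simulate", "expression.tsv")),
                      unit = "TPM")
  ann <- read_annotations(need_file(outdir, "simulate", "annotations.csv"))
  lg <- log2_tpm(expr, pseudocount = config$preprocess$pseudocount)
  corrected <- correct_batch(lg, setNames(ann$batch, ann$sample_id))
  top <- top_variable_genes(corrected, n = config$preprocess$top_n)
  pca <- pca_embedding(corrected, k = 2)
  d <- stage_dir(outdir, "preprocess")
  write_matrix_tsv(corrected$values, file.path(d, "log2_corrected.tsv"), "gene_id")
  writeLines(top, file.path(d, "top_genes.txt"))
  write_df_csv(data.frame(sample_id = rownames(pca$scores), pca$scores),
               file.path(d, "pca.csv"))
  invisible(TRUE)
}

stage_cluster <- function(config, outdir, seed) {
  v <- read_matrix_tsv(need_file(outdir, "preprocess", "log2_corrected.tsv"))
  top <- readLines(need_file(outdir, "preprocess", "top_genes.txt"))
  cc <- config$cluster
  res <- consensus_cluster(v[top, , drop = FALSE], k_range = cc$k_min:cc$k_max,
                           n_resamples = cc$n_resamples,
                           sample_frac = cc$sample_frac, seed = seed,
                           delta_threshold = cc$delta_threshold)
  d <- stage_dir(outdir, "cluster")
  for (k in names(res$consensus))
    write_matrix_tsv(res$consensus[[k]], file.path(d, sprintf("consensus_k%s.tsv", k)),
                     "sample_id")
  assign_df <- data.frame(sample_id = names(res$assignments[[1]]))
  for (k in names(res$assignments))
    assign_df[[paste0("k", k)]] <- unname(res$assignments[[k]])
  assign_df$cluster <- unname(res$assignments[[as.character(res$chosen_k)]])
  write_df_csv(assign_df, file.path(d, "assignments.csv"))
  write_df_csv(data.frame(k = res$k_range, cdf_area = unname(res$cdf_area),
                          delta_area = unname(res$delta_area)),
               file.path(d, "cdf.csv"))
  write_df_csv(data.frame(sample_id = names(res$silhouette),
                          width = unname(res$silhouette)),
               file.path(d, "silhouette.csv"))
  writeLines(as.character(res$chosen_k), file.path(d, "chosen_k.txt"))
  sig <- sigclust_pairwise(v[top, , drop = FALSE],
                           res$assignments[[as.character(res$chosen_k)]],
                           n_sim = cc$sigclust_n_sim, seed = seed)
  write_df_csv(sig, file.path(d, "sigclust.csv"))
  invisible(TRUE)
}

# The progressive cluster is the one with the highest proportion of
# WHO grade II/III samples (ties broken by cluster size, then id).
progressive_cluster <- function(assignments, grade) {
  high <- grade %in% c("II", "III")
  tab <- tapply(high, assignments, mean)
  sizes <- table(assignments)[names(tab)]
  names(tab)[c_order(-unname(tab), -as.vector(sizes), names(tab))][1]
}

stage_signature <- function(config, outdir, seed) {
  v <- read_matrix_tsv(need_file(outdir, "preprocess", "log2_corrected.tsv"))
  assign <- read.csv(need_file(outdir, "cluster", "assignments.csv"),
                     stringsAsFactors = FALSE)
  ann <- read_annotations(need_file(outdir, "simulate", "annotations.csv"))
  ann <- ann[match(assign$sample_id, ann$sample_id), ]
  prog <- progressive_cluster(assign$cluster, ann$grade)
  deg <- moderated_de(v[, assign$sample_id, drop = FALSE],
                      assign$cluster, target = as.integer(prog))
  sig <- extract_signature(deg, fdr = config$signature$fdr,
                           lfc = config$signature$lfc, name = "PROGRESSIVE")
  d <- stage_dir(outdir, "signature")
  write_df_csv(as.data.frame(deg), file.path(d, "deg_progressive.tsv"))
  write_gmt(sig, file.path(d, "signature.gmt"))
  writeLines(as.character(prog), file.path(d, "progressive_cluster.txt"))
  invisible(TRUE)
}

stage_score <- function(config, outdir, seed) {
  v <- read_matrix_tsv(need_file(outdir, "preprocess", "log2_corrected.tsv"))
  sets <- read_gmt(need_file(outdir, "signature", "signature.gmt"))
  sig <- signature_set("PROGRESSIVE", up = sets$PROGRESSIVE_UP,
                       down = sets$PROGRESSIVE_DN)
  panels <- read_gmt(need_file(outdir, "simulate", "panels.gmt"))
  wdf <- read.csv(need_file(outdir, "simulate", "stemness_weights.csv"),
                  stringsAsFactors = FALSE)
  weights <- setNames(wdf$weight, wdf$gene_id)
  es <- ssgsea(v, setNames(list(sig$up, sig$down), c("up", "down")),
               tau = config$score$tau, normalize = config$score$normalize)
  mp <- es["up", ] - es["down", ]
  si <- stemness_index(v, weights)
  imm <- immune_scores(v, panels)
  scores <- data.frame(sample_id = colnames(v), mpscore = unname(mp),
                       ssgsea_up = unname(es["up", ]),
                       ssgsea_down = unname(es["down", ]),
                       si = unname(si[colnames(v)]))
  scores <- cbind(scores, as.data.frame(imm[colnames(v), , drop = FALSE]))
  write_df_csv(scores, file.path(stage_dir(outdir, "score"), "scores.csv"))
  invisible(TRUE)
}

stage_methyl <- function(config, outdir, seed) {
  beta <- read_matrix_tsv(need_file(outdir, "simulate", "beta.tsv"))
  arms <- read_matrix_tsv(need_file(outdir, "simulate", "arms.tsv"))
  scores <- read.csv(need_file(outdir, "score", "scores.csv"),
                     stringsAsFactors = FALSE)
  assign <- read.csv(need_file(outdir, "cluster", "assignments.csv"),
                     stringsAsFactors = FALSE)
  mc <- config$methyl
  groups <- setNames(assign$cluster, assign$sample_id)[colnames(beta)]
  cimp <- call_cimp(beta, groups, sd_threshold = mc$sd_threshold,
                    hyper_beta = mc$hyper_beta)
  loss_1p <- call_arm_loss(arms, "chr1p", threshold = mc$arm_threshold)
  loss_22q <- call_arm_loss(arms, "chr22q", threshold = mc$arm_threshold)
  si <- setNames(scores$si, scores$sample_id)[rownames(arms)]
  subtype <- suppressWarnings(
    assign_methylation_subtype(loss_1p, loss_22q, si,
                               si_threshold = mc$si_threshold))
  d <- stage_dir(outdir, "methyl")
  write_df_csv(data.frame(group = names(cimp), cimp = unname(cimp)),
               file.path(d, "cimp.csv"))
  write_df_csv(data.frame(sample_id = rownames(arms),
                          loss_chr1p = unname(loss_1p),
                          loss_chr22q = unname(loss_22q)),
               file.path(d, "arm_loss.csv"))
  write_df_csv(data.frame(sample_id = rownames(arms), si = unname(si),
                          methyl_subtype = unname(subtype)),
               file.path(d, "methyl_assignments.csv"))
  invisible(TRUE)
}

stage_survival <- function(config, outdir, seed) {
  surv <- read.csv(need_file(outdir, "simulate", "survival.csv"),
                   stringsAsFactors = FALSE)
  scores <- read.csv(need_file(outdir, "score", "scores.csv"),
                     stringsAsFactors = FALSE)
  surv <- merge(surv, scores[, c("sample_id", "mpscore")], by = "sample_id")
  groups <- dichotomize_mpscore(setNames(surv$mpscore, surv$sample_id))
  km <- km_estimate(surv$time, surv$event, groups)
  lr <- logrank_test(surv$time, surv$event, groups)
  cox <- cox_fit(surv, c("mpscore", "location", "sex", "mib1"),
                 ties = config$survival$ties)
  d <- stage_dir(outdir, "survival")
  write_df_csv(as.data.frame(km), file.path(d, "km.csv"))
  jsonlite::write_json(c(lr, list(cutpoint = attr(groups, "cutpoint"))),
                       file.path(d, "logrank.json"), auto_unbox = TRUE, digits = NA)
  write_df_csv(as.data.frame(cox), file.path(d, "cox.csv"))
  invisible(TRUE)
}
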