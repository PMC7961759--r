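# mprog — meningioma progression subtyping and the MPscore

Meningioma is the most common primary CNS tumor. Most cases are WHO grade
I and cured by resection, but a subset recurs and progresses, and
histopathological grade alone does not capture that risk. `mprog`
implements a transcriptome-based progression analysis for bulk RNA-seq
meningioma cohorts:

1. **Consensus subtype discovery.** Resampled average-linkage
   hierarchical clustering on the 1 − Pearson distance over the top 2000
   variable genes; the number of subtypes k is chosen from the relative
   increase of the consensus CDF area, and cluster significance is tested
   pairwise with a SigClust-style Monte Carlo test (2-means cluster index
   against a spiked-Gaussian null).
2. **Progressive-subtype signature.** One-vs-rest empirical-Bayes
   moderated t-tests (inverse-gamma variance prior fitted on log s²)
   define the up/down signature of the progressive subtype at
   FDR < 0.05 and |log2FC| > 2.
3. **MPscore.** A first-principles single-sample GSEA (rank-weighted
   running sum, weight exponent τ = 0.25) scores each sample against the
   signature:

   MPscore(s) = ssGSEA_s(up signature) − ssGSEA_s(down signature)

4. **Companion scores.** Spearman-correlation stemness index (SI,
   rescaled to [0, 1]), MCP-counter-style immune population scores (mean
   log2 marker expression), random-forest marker ranking with
   10-fold-CV recursive elimination, and single-gene ROC/AUC.
5. **Methylation decision rules.** CIMP calling (variable CpG loci,
   within-group SD > 0.2, majority hypermethylated), arm-level
   copy-number loss (arm mean < 0.1), and the rule-based subtype
   assignment: 1p+22q loss ⇒ subtype 3; 22q loss alone ⇒ subtype 2;
   SI > 0.5 ⇒ subtype 4; no loss ⇒ subtype 1.
6. **Survival validation.** Median-split Kaplan–Meier curves, log-rank
   test, and multivariable Cox regression (MPscore + location + sex +
   MIB-1, Breslow ties).

Because the original cohorts live behind GEO accessions, the package
ships a **synthetic cohort generator** (`simulate_cohort()`) that
emulates the study's statistical structure — 179 samples in four subtypes
(67/38/59/15), grade II/III concentrated in subtype 3, planted up/down
signature genes, two batches, immune marker structure, subtype-3 CpG
hypermethylation, chr1p/chr22q losses, and a recurrence hazard ratio of 3
for subtype 3 — so the whole pipeline runs and is tested end-to-end
without downloads.

## Worked example

```r
library(mprog)

cohort <- simulate_cohort(cohort_spec(seed = 101))
lg     <- correct_batch(log2_tpm(cohort$expression),
                        setNames(cohort$annotations$batch,
                                 cohort$annotations$sample_id))
top    <- top_variable_genes(lg, 2000)

cc <- consensus_cluster(lg$values[top, ], k_range = 2:6,
                        n_resamples = 500, seed = 7)
cc
#> <consensus_result> k in {2, 3, 4, 5, 6}, 500 resamples (frac 0.80)
#>   chosen k = 4; delta areas: 2=0.178, 3=2.189, 4=0.241, 5=0.006, 6=0.006
```

The four planted subtypes are recovered exactly (adjusted Rand index 1.0
against the generator's truth), and k = 4 is selected because the
consensus CDF area stops improving beyond four clusters. Continuing:

```r
deg <- moderated_de(lg, cc$assignments[["4"]] == 3)
sig <- extract_signature(deg, fdr = 0.05, lfc = 2)
mp  <- mpscore(lg, sig)
tapply(mp, cohort$annotations$subtype, mean)
#>        1        2        3        4
#> ~400     ~413     ~1741    ~419
```

The progressive subtype's mean MPscore exceeds every other subtype
(t-test p < 1e-26 in the bundled acceptance run), and a median split of
the MPscore stratifies recurrence-free survival (log-rank p = 0.038 at
seed 1), with the standardized MPscore significant in the multivariable
Cox model (p = 9e-4).

A full run with per-stage outputs and a JSON manifest:

```r
run_pipeline(pipeline_config(seed = 1), "mprog_run")
```

or from a shell: `Rscript inst/cli/mprog.R all --outdir mprog_run --seed 1`.

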