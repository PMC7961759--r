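# Two well-separated Gaussian point clouds (genes x samples).
two_clouds <- function(n1 = 8, n2 = 8, g = 40, sep = 20, seed = 1) {
  set.seed(seed)
  p1 <- rep(c(1, 0), length.out = g)       # distinct correlated profiles
  p2 <- rep(c(0, 1), length.out = g)
  v <- cbind(matrix(rnorm(g * n1), g) + sep * p1,
             matrix(rnorm(g * n2), g) + sep * p2)
  dimnames(v) <- list(paste0("g", seq_len(g)), paste0("s", seq_len(n1 + n2)))
  v
}

test_that("perfectly separated clouds give a 0/1 consensus matrix", {
  v <- two_clouds()
  res <- consensus_cluster(v, k_range = 2:3, n_resamples = 40, seed = 2)
  cm <- res$consensus[["2"]]
  truth <- rep(1:2, each = 8)
  same <- outer(truth, truth, "==")
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))
  expect_equal(unname(diag(cm)), rep(1, 16))
  expect_true(isSymmetric(cm))
})

test_that("one full-sample resample yields the 0/1 co-membership matrix", {
  v <- two_clouds(5, 5, g = 20)
  res <- consensus_cluster(v, k_range = 2:3, n_resamples = 1, sample_frac = 1,
                           seed = 1)
  hc <- hclust(as.dist(1 - cor(v)), method = "average")
  for (k in 2:3) {
    cl <- cutree(hc, k)
    expect_equal(unname(res$consensus[[as.character(k)]]),
                 unname(outer(cl, cl, "==") * 1))
  }
})

test_that("consensus matrices are symmetric with unit diagonal in [0, 1]", {
  co <- simulate_cohort(small_spec())
  cb <- cohort_log2(co)
  v <- cb$values[top_variable_genes(cb, 300), ]
  res <- consensus_cluster(v, k_range = 2:5, n_resamples = 40, seed = 5)
  for (cm in res$consensus) {
    expect_true(isSymmetric(cm))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_true(all(diag(cm) == 1))
  }
  # assignments cover all samples at each k
  for (k in names(res$assignments))
    expect_setequal(names(res$assignments[[k]]), colnames(v))
})

test_that("never co-drawn pairs raise an instructive error", {
  v <- two_clouds(6, 6, g = 10)
  expect_error(consensus_cluster(v, k_range = 2:3, n_resamples = 1,
                                 sample_frac = 0.5, seed = 1),
               "n_resamples")
})

test_that("delta areas follow the definition and drive k selection", {
  fake <- structure(list(cdf_area = c(`2` = 0.2, `3` = 0.3, `4` = 0.39,
                                      `5` = 0.392),
                         k_range = 2:5),
                    class = "consensus_result")
  d <- unname(mprog:::delta_area(fake))
  expect_equal(d, c(0.2, 0.5, 0.3, 0.0051282051282), tolerance = 1e-10)
  expect_equal(select_k(fake, delta_threshold = 0.025), 4)
  expect_equal(select_k(fake, delta_threshold = 0.4), 3)
})

test_that("pure noise selects the smallest k with a warning", {
  set.seed(8)
  v <- matrix(rnorm(60 * 30), 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  res <- suppressWarnings(consensus_cluster(v, k_range = 2:5, n_resamples = 80,
                                            seed = 3))
  expect_warning(select_k(res), "no consensus structure")
  expect_equal(suppressWarnings(select_k(res)), 2)
})

test_that("subtype recovery improves with planted effect size", {
  aris <- vapply(c(0, 1, 2), function(eff) {
    co <- simulate_cohort(small_spec(effect_log2fc = eff))
    cb <- cohort_log2(co)
    v <- cb$values[top_variable_genes(cb, 300), ]
    res <- consensus_cluster(v, k_range = 2:5, n_resamples = 60, seed = 11)
    ari(res$assignments[["4"]], co$truth$subtype)
  }, numeric(1))
  expect_true(all(diff(aris) >= -0.05))
  expect_lt(aris[1], 0.1)
  expect_gt(aris[3], 0.9)
})

test_that("silhouette widths match the exhaustive oracle on a 5-point toy", {
  d <- matrix(0, 5, 5)
  d[upper.tri(d)] <- c(0.1, 0.9, 0.8, 0.85, 0.95, 0.7, 0.2, 0.15, 0.9, 0.25)
  d <- d + t(d)
  cl <- c(1, 1, 2, 2, 2)
  widths <- silhouette_widths(1 - d, cl)
  expect_equal(unname(widths), silhouette_oracle(d, cl), tolerance = 1e-12)

  # permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  wp <- silhouette_widths((1 - d)[perm, perm], cl[perm])
  expect_equal(unname(wp), unname(widths[perm]), tolerance = 1e-12)
})

test_that("silhouette is 1 for perfectly separated consensus blocks", {
  cm <- rbind(cbind(matrix(1, 4, 4), matrix(0, 4, 4)),
              cbind(matrix(0, 4, 4), matrix(1, 4, 4)))
  widths <- silhouette_widths(cm, rep(1:2, each = 4))
  expect_equal(unname(widths), rep(1, 8))
  expect_warning(silhouette_widths(cm, c(1, rep(2, 7))), "singleton")
  expect_error(silhouette_widths(cm, rep(1, 8)), "2 clusters")
})

test_that("sigclust saturates on separated clusters and errors when degenerate", {
  v <- two_clouds(10, 10, g = 30, sep = 10, seed = 9)
  res <- sigclust_pairwise(v, rep(1:2, each = 10), n_sim = 60, seed = 4)
  expect_lte(res$p_value, 1 / 61)
  expect_true(res$cluster_index > 0 && res$cluster_index <= 1)

  flat <- matrix(1, 10, 12, dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  expect_error(sigclust_pairwise(flat, rep(1:2, each = 6), n_sim = 10, seed = 1),
               "degenerate")
  expect_error(sigclust_pairwise(v, c(rep(1, 2), rep(2, 18)), n_sim = 10, seed = 1),
               ">= 3 samples")
})

test_that("all pairwise cluster tests are significant on the planted cohort", {
  co <- simulate_cohort(small_spec())
  cb <- cohort_log2(co)
  v <- cb$values[top_variable_genes(cb, 300), ]
  res <- sigclust_pairwise(v, co$truth$subtype[colnames(v)], n_sim = 100,
                           seed = 6)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_value < 0.05))
})

test_that("average-linkage merge heights are non-decreasing", {
  co <- simulate_cohort(small_spec())
  cb <- cohort_log2(co)
  hc <- hclust(as.dist(1 - cor(cb$values)), method = "average")
  expect_true(all(diff(hc$height) >= -1e-12))
})
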