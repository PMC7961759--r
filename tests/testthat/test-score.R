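test_that("ssgsea matches the closed-form 4-gene example", {
  expr <- matrix(c(4, 3, 2, 1), 4, 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
  # set = top gene, tau = 0: P_in steps (1,1,1,1), P_out (0,1/3,2/3,1) -> 2
  expect_equal(unname(ssgsea(expr, list(top = "g1"), tau = 0)[1, 1]), 2)
  expect_error(ssgsea(expr, list(none = "zz")), "no overlap")
  expect_error(ssgsea(expr, list(all = paste0("g", 1:4))), "all measured genes")
})

test_that("ssgsea equals the brute-force walker on random instances", {
  set.seed(1)
  for (i in 1:40) {
    e <- setNames(rnorm(50), sprintf("g%02d", 1:50))
    set <- sample(names(e), sample(3:20, 1))
    ours <- unname(ssgsea(e, list(s = set), tau = 0.25))
    expect_equal(ours, ssgsea_oracle(e, set, 0.25), tolerance = 1e-10)
  }
  # uniformly interleaved set: near-zero enrichment
  e <- setNames(20:1, sprintf("g%02d", 1:20))
  inter <- sprintf("g%02d", seq(1, 20, by = 2))
  expect_equal(unname(ssgsea(e, list(s = inter), tau = 0)),
               ssgsea_oracle(e, inter, 0), tolerance = 1e-12)
  expect_lt(abs(unname(ssgsea(e, list(s = inter), tau = 0))), 1.01)
})

test_that("ssgsea is invariant to monotone transforms of expression", {
  set.seed(2)
  e <- setNames(rexp(30), paste0("g", 1:30))
  set <- sample(names(e), 8)
  a <- unname(ssgsea(e, list(s = set), tau = 0.25))
  b <- unname(ssgsea(log1p(e) * 7 + 2, list(s = set), tau = 0.25))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("cohort range normalization rescales per set", {
  set.seed(3)
  v <- matrix(rnorm(40 * 6), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  set <- list(s = paste0("g", 1:8))
  raw <- ssgsea(v, set)
  norm <- ssgsea(v, set, normalize = TRUE)
  expect_equal(unname(norm["s", ]), unname(raw["s", ] / diff(range(raw["s", ]))))
})

test_that("mpscore is the up-minus-down difference with exact symmetries", {
  set.seed(4)
  v <- matrix(rnorm(60 * 8), 60,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  up <- paste0("g", 1:10); dn <- paste0("g", 21:35)
  sig <- signature_set("sig", up, dn)
  mp <- mpscore(v, sig)
  es <- ssgsea(v, list(u = up, d = dn))
  expect_equal(unname(mp), unname(es["u", ] - es["d", ]), tolerance = 1e-12)
  # antisymmetric under swapping up/down
  expect_equal(unname(mpscore(v, signature_set("r", dn, up))), -unname(mp))
  # identical up/down membership scores exactly zero
  same <- ssgsea(v, list(a = up, b = up))
  expect_equal(unname(same["a", ] - same["b", ]), rep(0, 8))
  expect_error(mpscore(v, signature_set("bad", up, character(0))), "non-empty")
})

test_that("raising up-gene expression never decreases the MPscore", {
  set.seed(5)
  v <- matrix(rnorm(50 * 4), 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  sig <- signature_set("sig", paste0("g", 1:8), paste0("g", 40:50))
  base <- mpscore(v, sig)
  for (bump in c(0.5, 2, 5)) {
    v2 <- v
    v2[sig$up, 1] <- v2[sig$up, 1] + bump
    expect_gte(mpscore(v2, sig)[1], base[1] - 1e-12)
  }
})

test_that("mpscore of subtype 3 dominates on the planted cohort", {
  co <- simulate_cohort(small_spec())
  cb <- cohort_log2(co)
  mp <- mpscore(cb, signature_set("planted", co$truth$signature_up,
                                  co$truth$signature_down))
  sub <- co$annotations$subtype
  means <- tapply(mp, sub, mean)
  expect_equal(unname(which.max(means)), 3)
  for (s in c(1, 2, 4))
    expect_lt(t.test(mp[sub == 3], mp[sub == s])$p.value, 0.01)
})

test_that("stemness index is the rescaled Spearman correlation", {
  set.seed(6)
  w <- setNames(rnorm(20), paste0("g", 1:20))
  perfect <- rank(w)                       # same ranks as the weights
  anti <- rank(-w)
  mid <- seq_along(w)[order(sample(20))]   # random third sample
  v <- cbind(s1 = perfect, s2 = anti, s3 = mid)
  rownames(v) <- names(w)
  si <- stemness_index(v, w)
  expect_equal(unname(si["s1"]), 1)
  expect_equal(unname(si["s2"]), 0)
  expect_true(all(si >= 0 & si <= 1))

  # three samples with raw correlations {-1, 0, 1} rescale to {0, .5, 1}
  raw <- apply(v, 2, function(col) cor(w, col, method = "spearman"))
  expect_equal(unname((raw - min(raw)) / diff(range(raw))), unname(si))

  expect_error(stemness_index(v[1:5, ], w[1:5]), ">= 10")
  v0 <- v; v0[, 2] <- 3
  expect_error(stemness_index(v0, w), "zero-variance")
})

test_that("immune scores are marker means on the log2 scale", {
  v <- rbind(m1 = c(1, 2), m2 = c(3, 6), other = c(9, 9))
  colnames(v) <- c("s1", "s2")
  sc <- immune_scores(v, list(popA = c("m1", "m2"), popB = "m1"))
  expect_equal(sc[, "popA"], c(s1 = 2, s2 = 4))
  expect_equal(sc[, "popB"], c(s1 = 1, s2 = 2))
  # doubling TPM adds exactly 1 on the log2 scale
  m <- expr_matrix(matrix(c(4, 8), 1, dimnames = list("m1", c("a", "b"))),
                   unit = "TPM")
  lg <- log2_tpm(m, pseudocount = 0)
  sc2 <- immune_scores(lg, list(p = "m1"))
  expect_equal(unname(sc2["b", "p"] - sc2["a", "p"]), 1)
  expect_error(immune_scores(v, list(ghost = "nope")), "ghost")
})

test_that("cytotoxic lymphocytes rank subtype 3 first on the planted cohort", {
  co <- simulate_cohort(small_spec())
  cb <- cohort_log2(co)
  sc <- immune_scores(cb, co$truth$immune_panels)
  means <- tapply(sc[, "Cytotoxic_lymphocytes"], co$annotations$subtype, mean)
  expect_equal(unname(which.max(means)), 3)
})

test_that("roc_auc follows the Mann-Whitney identity with ties at 0.5", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(7)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, l), auc_oracle(s, l), tolerance = 1e-12)
  # complement and monotone-transform invariances
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
})

test_that("roc_auc agrees with pROC at fixed direction", {
  set.seed(8)
  s <- rnorm(60); l <- rbinom(60, 1, 0.4)
  ours <- roc_auc(s, l)
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, direction = "<",
                                           quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("group_compare matches hand-computed sums of squares", {
  # 3-group toy: groups {1,2,3}, {2,4,6}, {5,7,9}
  vals <- c(1, 2, 3, 2, 4, 6, 5, 7, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  # hand computation: SSB = 3[(2-4.333..)^2+(4-4.333..)^2+(7-4.333..)^2]
  gm <- mean(vals)
  ssb <- 3 * sum((c(2, 4, 7) - gm)^2)
  ssw <- sum((vals - rep(c(2, 4, 7), each = 3))^2)
  f_manual <- (ssb / 2) / (ssw / 6)
  res <- group_compare(vals, grp)
  expect_equal(res$f, f_manual, tolerance = 1e-12)
  expect_equal(nrow(res$tukey), 3)

  # two groups: F equals the square of the pooled t
  v2 <- c(1.2, 0.8, 1.5, 3.1, 2.9, 3.3)
  g2 <- rep(c("x", "y"), each = 3)
  tt <- t.test(v2[1:3], v2[4:6], var.equal = TRUE)$statistic
  expect_equal(group_compare(v2, g2)$f, unname(tt^2), tolerance = 1e-10)

  # identical constants: F = 0, p = 1 by convention
  res0 <- group_compare(rep(5, 9), grp)
  expect_equal(res0$f, 0)
  expect_equal(res0$p_value, 1)
  expect_error(group_compare(1:5, c("a", "a", "b", "b", "c")), "at least 2")
})

test_that("random forest finds a planted perfect separator", {
  set.seed(9)
  v <- matrix(rnorm(301 * 40), 301,
              dimnames = list(c("sep", paste0("n", 1:300)), paste0("s", 1:40)))
  lab <- rep(c(3, 1), each = 20)
  v["sep", lab == 3] <- v["sep", lab == 3] + 6
  mr <- rf_marker_ranking(v, lab, target = 3, n_trees = 200, cv_folds = 5,
                          seed = 2)
  expect_equal(mr$importance$gene[1], "sep")
  expect_lte(mr$cv_error$error[mr$cv_error$n_var == 1], 0.05)
  # retained-variable counts shrink by about 1/step per round
  nv <- sort(mr$cv_error$n_var, decreasing = TRUE)
  expect_true(all(diff(nv) < 0))
  expect_error(rf_marker_ranking(v, lab, target = 3, step = 1), "step")
})

test_that("permuted labels give no significant importance", {
  set.seed(10)
  v <- matrix(rnorm(200 * 40), 200,
              dimnames = list(paste0("n", 1:200), paste0("s", 1:40)))
  lab <- sample(rep(c(3, 1), each = 20))
  mr <- rf_marker_ranking(v, lab, target = 3, n_trees = 200, cv = FALSE,
                          seed = 3)
  # scaled importance is a z-score; nothing should clear z = 4
  expect_lt(mr$importance$importance[1], 4)
  expect_null(mr$cv_error)
})

test_that("a strongly down-shifted marker separates subtype 3 by AUC", {
  set.seed(11)
  n <- 80
  lab <- rep(c(3, 1), each = n / 2)
  marker <- rnorm(n, 0, 1) - 2 * (lab == 3)   # planted effect 2 sd
  expect_gte(roc_auc(-marker, lab == 3), 0.85)
})
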