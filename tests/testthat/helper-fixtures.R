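# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, exhaustive enumeration) and independent of
# the package implementation.

# A small, fast cohort spec for module-level tests.
small_spec <- function(...) {
  args <- list(
    n_per_subtype = c(20L, 15L, 20L, 10L), n_genes = 600L,
    n_signature_up = 10L, n_signature_down = 15L,
    n_program_other = c(40L, 30L, 30L),
    n_stemness = 40L,
    cpg_spec = list(n_cpg = 400, n_variable = 80, shift = 0.3),
    seed = 42L
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_spec, args)
}

# log2 + batch-corrected expression of a cohort.
cohort_log2 <- function(co) {
  correct_batch(log2_tpm(co$expression),
                setNames(co$annotations$batch, co$annotations$sample_id))
}

# Planted one-vs-rest log2 contrast for subtype `st` from the truth shift
# matrix (weighted by subtype sizes).
planted_contrast <- function(co, st = 3) {
  sh <- co$truth$shift
  n <- co$spec$n_per_subtype
  rest <- setdiff(1:4, st)
  sh[, st] - as.vector(sh[, rest] %*% n[rest]) / sum(n[rest])
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Independent running-sum ssGSEA walker (explicit loop).
ssgsea_oracle <- function(expr, set, tau) {
  r <- rank(expr, ties.method = "average")
  ord <- order(-r, names(expr), method = "radix")
  ids <- names(expr)[ord]
  w <- r[ord]^tau
  h <- ids %in% set
  tot_in <- sum(w[h]); tot_out <- sum(!h)
  es <- 0; pin <- 0; pout <- 0
  for (i in seq_along(ids)) {
    if (h[i]) pin <- pin + w[i] / tot_in else pout <- pout + 1 / tot_out
    es <- es + (pin - pout)
  }
  unname(es)
}

# Exhaustive silhouette computation from a distance matrix.
silhouette_oracle <- function(d, cl) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
               numeric(1))
  out <- numeric(m)
  out[ord] <- qs
  out
}

# Exhaustive concordant-pair AUC.
auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
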