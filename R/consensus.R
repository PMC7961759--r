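#' Resampled consensus clustering
#'
#' Repeated average-linkage hierarchical clustering on the 1 - Pearson
#' correlation distance over subsampled sample sets. For each resample a
#' fraction of samples is drawn without replacement, clustered, and the
#' tree cut at each k in `k_range`; `consensus[i, j]` is the fraction of
#' co-draws in which samples i and j co-clustered. The final assignment at
#' each k is average-linkage clustering of `1 - consensus` cut at k.
#' The consensus CDF area and its relative increase (delta area) across k
#' drive model selection via [select_k()].
#'
#' @param x an [expr_matrix()] (log2 values recommended) or plain genes x
#'   samples matrix, typically restricted to [top_variable_genes()].
#' @param k_range integer vector of cluster counts (>= 2 values, max < n).
#' @param n_resamples number of subsampling iterations (default 1000).
#' @param sample_frac fraction of samples drawn per iteration (default 0.8).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param delta_threshold passed to [select_k()].
#' @return An object of class `consensus_result`: list with `consensus`
#'   (per-k matrices), `assignments` (per-k integer vectors),
#'   `cdf_area`, `delta_area`, `chosen_k`, `silhouette` (widths at
#'   `chosen_k`), `k_range`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 1000,
                              sample_frac = 0.8, seed = 1,
                              delta_threshold = 0.025) {
  v <- as_values(x)
  n <- ncol(v)
  if (n < 3) stopf("consensus clustering needs at least 3 samples")
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2) stopf("k_range must contain at least 2 values")
  if (any(k_range < 2)) stopf("k must be >= 2")
  if (max(k_range) >= n) stopf("max k (%d) must be smaller than the number of samples (%d)",
                               max(k_range), n)
  if (sample_frac <= 0 || sample_frac > 1) stopf("sample_frac must be in (0, 1]")
  if (n_resamples < 1) stopf("n_resamples must be >= 1")
  m <- ceiling(sample_frac * n)

  co_draw <- matrix(0, n, n)
  co_clust <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clust) <- as.character(k_range)

  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      d <- pearson_dist(v[, idx, drop = FALSE])
      hc <- hclust(d, method = "average")
      co_draw[idx, idx] <- co_draw[idx, idx] + 1
      for (k in k_range) {
        cl <- cutree(hc, k = k)
        same <- outer(cl, cl, "==")
        ck <- as.character(k)
        co_clust[[ck]][idx, idx] <- co_clust[[ck]][idx, idx] + same
      }
    }
  })

  off <- upper.tri(co_draw)
  if (any(co_draw[off] == 0))
    stopf("some sample pairs were never co-drawn; increase n_resamples")

  ids <- colnames(v) %||% paste0("S", seq_len(n))
  consensus <- lapply(co_clust, function(cc) {
    cm <- cc / pmax(co_draw, 1)
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  assignments <- lapply(seq_along(k_range), function(i) {
    hc <- hclust(as.dist(1 - consensus[[i]]), method = "average")
    setNames(cutree(hc, k = k_range[i]), ids)
  })
  names(assignments) <- as.character(k_range)

  cdf_area <- vapply(consensus, consensus_cdf_area, numeric(1))
  res <- structure(list(consensus = consensus, assignments = assignments,
                        cdf_area = cdf_area, k_range = k_range,
                        n_resamples = n_resamples, sample_frac = sample_frac),
                   class = "consensus_result")
  res$delta_area <- delta_area(res)
  res$chosen_k <- select_k(res, delta_threshold = delta_threshold)
  res$silhouette <- silhouette_widths(res$consensus[[as.character(res$chosen_k)]],
                                      res$assignments[[as.character(res$chosen_k)]])
  res
}

# 1 - Pearson correlation distance between the columns of v.
pearson_dist <- function(v) {
  as.dist(1 - cor(v, method = "pearson"))
}

# Area under the empirical CDF of the off-diagonal consensus entries,
# integrated over [0, 1].
consensus_cdf_area <- function(cm) {
  vals <- sort(cm[upper.tri(cm)])
  grid <- c(vals, 1)
  cdf <- seq_along(vals) / length(vals)
  sum(diff(c(0, grid)) * c(0, cdf))
}

delta_area <- function(result) {
  a <- result$cdf_area
  k <- result$k_range
  d <- numeric(length(k))
  d[1] <- a[1]
  if (length(k) > 1) d[-1] <- diff(a) / a[-length(a)]
  setNames(d, as.character(k))
}

#' Select the number of clusters from consensus CDF areas
#'
#' The area A(k) under the consensus CDF is computed per k; the relative
#' increase Delta(k) = (A(k) - A(k-1)) / A(k-1) (with Delta at the
#' smallest k set to its area) measures the stability gained by allowing
#' one more cluster. The chosen k is the largest k whose Delta is at
#' least `delta_threshold`. If no k beyond the smallest passes, the
#' smallest k is returned with a "no consensus structure" warning.
#'
#' Samples with no consensus structure are detected via the proportion of
#' ambiguous clustering (PAC): the fraction of off-diagonal consensus
#' entries strictly between 0.1 and 0.9. When every k has PAC above
#' `pac_threshold` the cohort is treated as unstructured: the smallest k
#' is returned with a "no consensus structure" warning. (The delta-area
#' statistic alone cannot flag noise: for an unstructured cohort the area
#' keeps growing mechanically with k.)
#'
#' @param result a [consensus_cluster()] result.
#' @param delta_threshold minimum relative area increase (default 0.025).
#' @param pac_threshold PAC above which a clustering is considered
#'   ambiguous (default 0.2).
#' @return Integer, the chosen k.
#' @export
select_k <- function(result, delta_threshold = 0.025, pac_threshold = 0.2) {
  stopifnot(inherits(result, "consensus_result"))
  if (length(result$k_range) < 2) stopf("k_range must contain at least 2 values")
  if (!is.null(result$consensus)) {
    pac <- vapply(result$consensus, function(cm) {
      off <- cm[upper.tri(cm)]
      mean(off > 0.1 & off < 0.9)
    }, numeric(1))
    if (all(pac > pac_threshold)) {
      warnf("no consensus structure at any k (all PAC above %g)", pac_threshold)
      return(result$k_range[1])
    }
  }
  d <- delta_area(result)
  ok <- d >= delta_threshold
  if (!any(ok[-1])) {
    warnf("no consensus structure beyond k = %d (all delta areas below %g)",
          result$k_range[1], delta_threshold)
    return(result$k_range[1])
  }
  max(result$k_range[ok])
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k in {%s}, %d resamples (frac %.2f)\n",
              paste(x$k_range, collapse = ", "), x$n_resamples, x$sample_frac))
  cat(sprintf("  chosen k = %d; delta areas: %s\n", x$chosen_k,
              paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area),
                    collapse = ", ")))
  invisible(x)
}

#' Silhouette widths on the consensus distance
#'
#' Standard silhouette widths s(i) = (b - a) / max(a, b) computed on the
#' distance 1 - consensus. Samples in singleton clusters get width 0 by
#' convention (with a warning).
#'
#' @param consensus samples x samples consensus matrix (entries in
#'   `[0, 1]`, unit diagonal).
#' @param assignments integer cluster ids, one per sample.
#' @return Numeric vector of per-sample widths in `[-1, 1]`, input order.
#' @export
silhouette_widths <- function(consensus, assignments) {
  consensus <- as.matrix(consensus)
  if (length(assignments) != nrow(consensus))
    stopf("assignments must have one entry per sample")
  if (length(unique(assignments)) < 2)
    stopf("silhouette needs at least 2 clusters")
  if (any(table(assignments) == 1))
    warnf("singleton cluster(s): silhouette width 0 by convention")
  sil <- cluster::silhouette(as.integer(factor(assignments)),
                             dmatrix = 1 - consensus)
  widths <- sil[, "sil_width"]
  names(widths) <- rownames(consensus)
  widths
}
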