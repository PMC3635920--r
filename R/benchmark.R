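#' Heatmap-style clustering of genes
#'
#' The expression-only baseline: Ward-linkage hierarchical clustering of the
#' genes on the correlation distance, cut at `n_clusters` (the sample-side
#' tree of a heatmap plays no role in the gene partition).
#'
#' @param G an [expression_matrix].
#' @param n_clusters number of clusters.
#' @return a [gene_partition].
#' @export
heatmap_clustering <- function(G, n_clusters) {
  stopifnot(inherits(G, "expression_matrix"))
  d <- correlation_distance(G)
  if (n_clusters < 2L || n_clusters > nrow(d)) stop("'n_clusters' out of range")
  if (n_clusters == nrow(d))
    return(gene_partition(stats::setNames(seq_len(nrow(d)), G$genes)))
  labels <- stats::cutree(.ward_tree(d), n_clusters)
  gene_partition(stats::setNames(labels, G$genes))
}

#' Topological overlap similarity of a soft-thresholded correlation network
#'
#' Unsigned adjacency `a = |cor|^beta` (zero diagonal); the topological
#' overlap between genes k and k' is
#' `(sum_u a_ku a_uk' + a_kk') / (min(k_k, k_k') + 1 - a_kk')` with `k_k`
#' the connectivity of gene k; the diagonal is 1 by convention.
#'
#' @param G an [expression_matrix].
#' @param beta soft-threshold power (>= 1, default 6).
#' @return symmetric similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(G, beta = 6) {
  stopifnot(inherits(G, "expression_matrix"), beta >= 1)
  A <- abs(gene_correlation(G))^beta
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  (TOM + t(TOM)) / 2
}

#' Coexpression-network (topological overlap) clustering of genes
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity `1 - TOM`, cut at `n_clusters`.
#'
#' @param G an [expression_matrix].
#' @param n_clusters number of clusters.
#' @param beta soft-threshold power (default 6).
#' @return a [gene_partition].
#' @export
wgcna_clustering <- function(G, n_clusters, beta = 6) {
  stopifnot(inherits(G, "expression_matrix"))
  TOM <- tom_similarity(G, beta)
  if (n_clusters < 2L || n_clusters > nrow(TOM))
    stop("'n_clusters' out of range")
  if (n_clusters == nrow(TOM))
    return(gene_partition(stats::setNames(seq_len(nrow(TOM)), G$genes)))
  tree <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  gene_partition(stats::setNames(stats::cutree(tree, n_clusters), G$genes))
}

#' Run the simulation benchmark of the three clustering strategies
#'
#' For each configuration and replicate: simulate a paired dataset, produce
#' three partitions at the configured cluster count (heatmap, coexpression
#' network, and the integrated chi-square-distance clustering), evaluate
#' each partition's clusters with the permutation tests, and aggregate the
#' mean percentages of significantly coexpressed / biologically homogeneous
#' / both clusters per method and configuration.
#'
#' @param grid data frame with columns `I`, `K`, `r`, `n_clusters` (one row
#'   per configuration); defaults to the single configuration
#'   `I = 10, K = 300, r = 1, n_clusters = 20`.
#' @param n_replicates simulated datasets per configuration.
#' @param B permutations per test (evaluation and filtering step).
#' @param alpha significance threshold.
#' @param alpha0 coexpression threshold of the filtering step.
#' @param method clustering algorithm for the integrated distance
#'   (`"hac"` or `"kmeans"`).
#' @param n_blocks,rho_within,rho_between passed to [simulation_config()].
#' @param seed top-level seed; per-replicate seeds are derived from it.
#' @return object of class `benchmark_result`: list with `results` (tidy
#'   data frame: config, method, replicate, pct_ci, pct_bhi, pct_both,
#'   n_singletons), `summary` (mean percentages per config x method) and
#'   `params`.
#' @export
run_benchmark <- function(grid = data.frame(I = 10L, K = 300L, r = 1L,
                                            n_clusters = 20L),
                          n_replicates = 20L, B = 500L, alpha = 0.05,
                          alpha0 = 0.10, method = "hac",
                          n_blocks = 20L, rho_within = 0.85,
                          rho_between = 0, seed = 1L) {
  stopifnot(all(c("I", "K", "r", "n_clusters") %in% names(grid)))
  rep_seeds <- .derive_seeds(seed, nrow(grid) * n_replicates)
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep in seq_len(n_replicates)) {
      idx <- idx + 1L
      cfg <- simulation_config(I = grid$I[g], K = grid$K[g],
                               n_blocks = n_blocks,
                               rho_within = rho_within,
                               rho_between = rho_between,
                               r = grid$r[g], seed = rep_seeds[[idx]])
      res <- .benchmark_replicate(cfg, grid$n_clusters[g], B = B,
                                  alpha = alpha, alpha0 = alpha0,
                                  method = method)
      res$I <- grid$I[g]; res$K <- grid$K[g]; res$r <- grid$r[g]
      res$replicate <- rep
      rows[[idx]] <- res
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    results[, c("pct_ci", "pct_bhi", "pct_both")],
    by = results[, c("I", "K", "r", "method")], FUN = mean)
  summary <- summary[order(summary$I, summary$K, summary$r, summary$method), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 params = list(n_replicates = n_replicates, B = B,
                               alpha = alpha, alpha0 = alpha0,
                               method = method, n_blocks = n_blocks,
                               rho_within = rho_within,
                               rho_between = rho_between, seed = seed)),
            class = "benchmark_result")
}

# One simulated dataset evaluated under the three clustering strategies.
# Null caches for the permutation tests are shared across the three
# evaluations of the same dataset (the null law depends on the data and the
# cluster size only).
.benchmark_replicate <- function(cfg, n_clusters, B, alpha, alpha0, method) {
  ds <- simulate_dataset(cfg)
  partitions <- list(
    heatmap = heatmap_clustering(ds$G, n_clusters),
    wgcna = wgcna_clustering(ds$G, n_clusters),
    integration = local({
      tc <- build_t_coexp(ds$G, ds$T, alpha0 = alpha0, B = B)
      D <- coexp_distance(tc)
      cluster_genes(D, n_clusters, method = method)
    }))
  C <- gene_correlation(ds$G)
  ones <- .bhi_ones(ds$T)
  cache <- .new_null_cache()
  out <- lapply(names(partitions), function(nm) {
    ev <- .evaluate_with_caches(C, ones, partitions[[nm]],
                                ds$G$genes, B, alpha, cache)
    data.frame(method = nm, pct_ci = ev$pct_ci, pct_bhi = ev$pct_bhi,
               pct_both = ev$pct_both, n_singletons = ev$n_singletons,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Summary-only partition evaluation against a precomputed correlation
# matrix and annotation lists, sharing one null cache.
.evaluate_with_caches <- function(C, ones, partition, genes, B,
                                  alpha, cache) {
  sig_ci <- sig_bhi <- sig_both <- 0L
  n_singletons <- 0L
  for (cl in partition$clusters) {
    idx <- match(cl, genes)
    m <- length(idx)
    if (m == 1L) { n_singletons <- n_singletons + 1L; next }
    ci_obs <- .offdiag_mean(C[idx, idx])
    bhi_obs <- .bhi_value(ones, idx)
    p_ci <- .perm_pvalue(ci_obs, .ci_null_values(C, m, B, cache))
    p_bhi <- .perm_pvalue(bhi_obs, .bhi_null_values(ones, m, B, cache))
    if (p_ci < alpha) sig_ci <- sig_ci + 1L
    if (p_bhi < alpha) sig_bhi <- sig_bhi + 1L
    if (p_ci < alpha && p_bhi < alpha) sig_both <- sig_both + 1L
  }
  n_cl <- partition$n_clusters
  list(pct_ci = 100 * sig_ci / n_cl, pct_bhi = 100 * sig_bhi / n_cl,
       pct_both = 100 * sig_both / n_cl, n_singletons = n_singletons)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("simulation benchmark (mean % of significant clusters):\n")
  print(x$summary, digits = 4)
  invisible(x)
}
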