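#' Coexpression indicator of a gene cluster
#'
#' Average of the pairwise Pearson correlations between the cluster's genes.
#' Equals 1 when all genes are perfectly positively correlated; its minimum
#' depends on cluster size (for the two-anti-correlated-sub-group worst
#' case: `-1/(n-1)` for even size `n`, `-1/n` for odd).
#'
#' @param x an [expression_matrix] or a precomputed gene correlation matrix.
#' @param cluster gene identifiers or indices (size >= 2).
#' @return the indicator value.
#' @export
coexpression_indicator <- function(x, cluster) {
  C <- if (inherits(x, "expression_matrix")) gene_correlation(x) else x
  idx <- if (is.character(cluster)) match(cluster, rownames(C))
         else as.integer(cluster)
  if (anyNA(idx)) stop("unknown gene(s) in 'cluster'")
  if (length(idx) < 2L) stop("cluster must contain at least 2 genes")
  .offdiag_mean(C[idx, idx])
}

# Sparse per-gene annotation lists used by the homogeneity indicator: the
# function indices each gene is annotated to, plus row margins.
.bhi_ones <- function(T) {
  X <- T$values
  list(ones = apply(X, 1L, function(row) which(row == 1L), simplify = FALSE),
       row_margins = T$row_margins, J = ncol(X))
}

# Biological homogeneity of a gene set: one minus the normalized chi-square
# statistic of the cluster's own gene x function subtable (margins of the
# submatrix; zero-margin columns drop out).  For a binary table
# X^2 = n (sum_{cells=1} 1/(r_k c_j) - 1) with n the subtable total, so only
# the clusters' annotation lists are touched.
.bhi_value <- function(ones, idx) {
  rm_idx <- ones$row_margins[idx]
  js <- unlist(ones$ones[idx], use.names = FALSE)
  n <- length(js)
  cj <- tabulate(js, nbins = ones$J)
  s <- sum(1 / (cj[js] * rep.int(rm_idx, rm_idx)))
  chi2 <- n * (s - 1)
  1 - chi2 / (n * (length(idx) - 1))
}

# B null homogeneity values for random size-m gene sets.
.bhi_null_values <- function(ones, size, B, cache = NULL) {
  key <- sprintf("bhi.%d.%d", size, B)
  hit <- .cache_get(cache, key)
  if (!is.null(hit)) return(hit)
  K <- length(ones$ones)
  vals <- vapply(seq_len(B), function(b)
    .bhi_value(ones, sample.int(K, size)), numeric(1))
  .cache_set(cache, key, vals)
}

#' Biological homogeneity indicator of a gene cluster
#'
#' One minus a normalized chi-square discrepancy (derived from Cramer's V)
#' of the cluster genes' functional profiles from independence: the
#' chi-square statistic of the cluster's own gene x function subtable,
#' divided by its association total times `card(K_l) - 1`.  Equals 1 when
#' all cluster genes share identical functional profiles, and 0 when no
#' function is shared by two cluster genes and each of their functions is
#' private to a single gene.  Always in `[0, 1]`.  Computed on the original
#' annotation matrix `T`, not on the coexpressed decomposition.
#'
#' @param T an [annotation_matrix][build_annotation_matrix].
#' @param cluster gene identifiers or indices (size >= 2, all annotated).
#' @return the indicator value.
#' @export
biological_homogeneity_indicator <- function(T, cluster) {
  stopifnot(inherits(T, "annotation_matrix"))
  idx <- if (is.character(cluster)) match(cluster, T$genes)
         else as.integer(cluster)
  if (anyNA(idx)) stop("unknown gene(s) in 'cluster'")
  if (length(idx) < 2L) stop("cluster must contain at least 2 genes")
  if (any(T$row_margins[idx] == 0L))
    stop("unannotated gene(s) in cluster: ",
         paste(T$genes[idx][T$row_margins[idx] == 0L], collapse = ", "))
  .bhi_value(.bhi_ones(T), idx)
}

#' Permutation p-value of a cluster indicator
#'
#' Builds the null distribution by drawing `B` gene sets of the cluster's
#' size without replacement from the full gene universe, evaluating the
#' indicator on each, and returning the proportion of null values strictly
#' exceeding the observed value (so the estimate can be exactly 0).  The
#' optional `(b+1)/(B+1)` correction avoids zero estimates.  Singleton
#' clusters are not tested and give `NA`.
#'
#' @param indicator function mapping a vector of gene indices to an
#'   indicator value.
#' @param universe_size number of genes draws are taken from.
#' @param cluster gene indices of the tested cluster.
#' @param B number of permutations (>= 1).
#' @param correct use the `(b+1)/(B+1)` estimator (default `FALSE`).
#' @return p-value in `[0, 1]`, or `NA` for a singleton cluster.
#' @export
permutation_pvalue <- function(indicator, universe_size, cluster, B = 1000L,
                               correct = FALSE) {
  if (length(cluster) < 2L) return(NA_real_)
  stopifnot(B >= 1L)
  obs <- indicator(cluster)
  null <- vapply(seq_len(B), function(b)
    indicator(sample.int(universe_size, length(cluster))), numeric(1))
  b <- sum(null > obs)
  if (correct) (b + 1) / (B + 1) else b / B
}

#' Evaluate every cluster of a gene partition
#'
#' Scores each cluster with the coexpression indicator and the biological
#' homogeneity indicator, attaches size-matched permutation p-values
#' (singleton clusters are not tested and are never significant), and
#' summarizes the percentage of clusters — over all clusters of the
#' partition — that are significantly coexpressed, significantly
#' biologically homogeneous, and both ("good candidates for
#' interpretation").
#'
#' @param G an [expression_matrix].
#' @param T an [annotation_matrix][build_annotation_matrix] over the same
#'   genes.
#' @param partition a [gene_partition].
#' @param B permutations per test.
#' @param alpha significance threshold applied to each p-value.
#' @param seed optional seed for the permutation draws.
#' @param correct passed to the p-value estimator (default plain
#'   proportion).
#' @return object of class `cluster_evaluation`: list with `clusters` (one
#'   row per cluster: size, ci, bhi, p-values, significance flags) and
#'   `summary` (pct_ci, pct_bhi, pct_both, n_clusters, n_singletons, alpha,
#'   B).
#' @export
evaluate_partition <- function(G, T, partition, B = 1000L, alpha = 0.05,
                               seed = NULL, correct = FALSE) {
  stopifnot(inherits(G, "expression_matrix"),
            inherits(T, "annotation_matrix"),
            inherits(partition, "gene_partition"))
  if (!setequal(partition$genes, G$genes) || !setequal(G$genes, T$genes))
    stop("partition, expression and annotation gene universes differ")
  if (!is.null(seed)) set.seed(seed)
  C <- gene_correlation(G)
  if (!identical(T$genes, G$genes))
    T <- .annotation_matrix(T$values[G$genes, , drop = FALSE])
  if (any(T$row_margins == 0L))
    stop("unannotated gene(s) present; reconcile universes first")
  ones <- .bhi_ones(T)
  cache <- .new_null_cache()
  K <- length(G$genes)

  rows <- lapply(seq_along(partition$clusters), function(ci) {
    genes <- partition$clusters[[ci]]
    idx <- match(genes, G$genes)
    m <- length(idx)
    if (m == 1L) {
      return(data.frame(cluster = ci, size = 1L, ci = NA_real_,
                        bhi = NA_real_, ci_pvalue = NA_real_,
                        bhi_pvalue = NA_real_, significant_ci = FALSE,
                        significant_bhi = FALSE, significant_both = FALSE))
    }
    ci_obs <- .offdiag_mean(C[idx, idx])
    bhi_obs <- .bhi_value(ones, idx)
    ci_null <- .ci_null_values(C, m, B, cache)
    bhi_null <- .bhi_null_values(ones, m, B, cache)
    p_ci <- if (correct) (sum(ci_null > ci_obs) + 1) / (B + 1)
            else .perm_pvalue(ci_obs, ci_null)
    p_bhi <- if (correct) (sum(bhi_null > bhi_obs) + 1) / (B + 1)
             else .perm_pvalue(bhi_obs, bhi_null)
    data.frame(cluster = ci, size = m, ci = ci_obs, bhi = bhi_obs,
               ci_pvalue = p_ci, bhi_pvalue = p_bhi,
               significant_ci = p_ci < alpha,
               significant_bhi = p_bhi < alpha,
               significant_both = p_ci < alpha && p_bhi < alpha)
  })
  clusters <- do.call(rbind, rows)
  n_cl <- nrow(clusters)
  summary <- data.frame(pct_ci = 100 * sum(clusters$significant_ci) / n_cl,
                        pct_bhi = 100 * sum(clusters$significant_bhi) / n_cl,
                        pct_both = 100 * sum(clusters$significant_both) / n_cl,
                        n_clusters = n_cl,
                        n_singletons = sum(clusters$size == 1L),
                        alpha = alpha, B = B)
  structure(list(clusters = clusters, summary = summary),
            class = "cluster_evaluation")
}

#' @export
print.cluster_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("partition evaluation: %d clusters (%d singletons)\n",
                     "  significantly coexpressed:            %5.1f%%\n",
                     "  significantly biologically homogeneous: %5.1f%%\n",
                     "  both (good candidates):               %5.1f%%\n"),
              s$n_clusters, s$n_singletons, s$pct_ci, s$pct_bhi, s$pct_both))
  invisible(x)
}

#' Write a per-cluster evaluation table
#' @param evaluation a `cluster_evaluation`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_evaluation <- function(evaluation, path, sep = "\t") {
  stopifnot(inherits(evaluation, "cluster_evaluation"))
  utils::write.table(evaluation$clusters, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
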