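#' Cut a classification tree at the partition with the highest relative loss
#' of inertia
#'
#' For `L` in `2..L_max` the total within-cluster inertia `W(L)` of the
#' `L`-cluster cut is computed from the squared distances (each cluster
#' contributes its within-pair distance sum divided by twice its size), and
#' the inertia loss of the step to `L` clusters is `D(L) = W(L-1) - W(L)`.
#' The returned partition is the one whose step loses the most inertia
#' relative to the next step, i.e. `L` maximizing `D(L)/D(L+1)` — the elbow
#' of the successive-loss sequence, the usual tree-cutting rule in
#' hierarchical ascending classification.  Ties break toward fewer
#' clusters; with two items the split is forced.
#'
#' @param tree an [stats::hclust] tree.
#' @param d the squared distance matrix the tree was built on.
#' @param L_max largest partition size considered (capped at `n - 1`).
#' @return integer vector of cluster labels.
#' @export
cut_tree_by_relative_inertia <- function(tree, d, L_max = 10L) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (n < 2L) stop("tree must cover at least 2 items")
  if (n == 2L) return(stats::cutree(tree, 2L))
  L_max <- max(2L, min(L_max, n - 1L))
  W <- vapply(seq_len(L_max + 1L), function(L)
    .partition_inertia(d, stats::cutree(tree, L)), numeric(1))
  gain <- pmax(W[-length(W)] - W[-1L], 0)   # gain[L] = W(L) - W(L+1)
  ratio <- vapply(2:L_max, function(L) {
    if (gain[L] <= .Machine$double.eps)
      return(if (gain[L - 1L] <= .Machine$double.eps) 1 else Inf)
    gain[L - 1L] / gain[L]
  }, numeric(1))
  L_best <- (2:L_max)[which.max(ratio)]
  stats::cutree(tree, L_best)
}

#' Test whether a biological function's gene set is coexpressed
#'
#' Filtering step of the decomposition: the coexpression indicator of the
#' function's gene set is compared with its permutation null (size-matched
#' gene sets drawn without replacement from all genes).  A function whose
#' p-value falls below `alpha0` is kept whole; others are split.
#'
#' @param x an [expression_matrix] or a precomputed gene correlation matrix.
#' @param genes character or integer vector of the function's genes
#'   (length >= 2).
#' @param B number of permutations.
#' @param alpha0 significance threshold for declaring coexpression
#'   (default 0.10).
#' @param cache optional internal null cache (shared across same-sized
#'   functions).
#' @return list with `is_coexpressed`, `p_value` and the observed `ci`.
#' @export
test_function_coexpression <- function(x, genes, B = 500L, alpha0 = 0.10,
                                       cache = NULL) {
  C <- if (inherits(x, "expression_matrix")) gene_correlation(x) else x
  idx <- if (is.character(genes)) match(genes, rownames(C)) else as.integer(genes)
  if (anyNA(idx)) stop("unknown gene(s) in 'genes'")
  m <- length(idx)
  if (m < 2L) stop("a singleton function cannot be tested for coexpression")
  obs <- .offdiag_mean(C[idx, idx])
  null <- .ci_null_values(C, m, B, cache)
  p <- .perm_pvalue(obs, null)
  list(is_coexpressed = p < alpha0, p_value = p, ci = obs)
}

#' Decompose biological functions into coexpressed biological functions
#'
#' For each function `j` with gene set `K^j`: the filtering step tests the
#' set's coexpression (see [test_function_coexpression()]); a coexpressed
#' function is conserved as a single column, otherwise the genes of `K^j`
#' are clustered hierarchically (Ward linkage on the correlation distance)
#' and the tree is cut by the relative loss of inertia, splitting the
#' function's column into one column per coexpressed sub-cluster.  The
#' columns of all functions are juxtaposed in the original function order;
#' within a function sub-clusters are ordered by decreasing size.
#'
#' The result keeps the margin structure of `T`: for every function the
#' sub-cluster column margins sum to the function's column margin, and row
#' margins and the total number of associations are unchanged.
#'
#' @param G an [expression_matrix].
#' @param T an [annotation_matrix][build_annotation_matrix] over the same
#'   gene universe; every function must annotate at least 2 genes (see
#'   [filter_functions()]).
#' @param alpha0 coexpression threshold for the filtering step; `alpha0 >= 1`
#'   skips testing and conserves every function whole.
#' @param B permutations for the filtering step.
#' @param L_max cap on the number of sub-clusters per function.
#' @param seed optional integer seed making the permutation draws
#'   reproducible.
#' @return object of class `coexp_matrix`: list with `values` (binary matrix,
#'   `function::l` column names), `genes`, `col_function`, `col_subcluster`,
#'   `col_margins` (`card(K_l^j)`), `row_margins`, `total`, and `partitions`
#'   (per function: `fun`, `p_value`, `coexpressed_whole`, `L`,
#'   `sub_clusters`).
#' @export
build_t_coexp <- function(G, T, alpha0 = 0.10, B = 500L, L_max = 10L,
                          seed = NULL) {
  stopifnot(inherits(G, "expression_matrix"),
            inherits(T, "annotation_matrix"))
  if (!setequal(G$genes, T$genes))
    stop("expression and annotation gene universes differ")
  if (!identical(G$genes, T$genes)) {
    T <- .annotation_matrix(T$values[G$genes, , drop = FALSE])
  }
  if (length(T$functions) == 0L) stop("annotation matrix has no functions")
  if (any(T$col_margins < 2L))
    stop("every function must annotate at least 2 genes; ",
         "apply filter_functions() first")
  if (!is.null(seed)) set.seed(seed)
  C <- gene_correlation(G)
  cache <- .new_null_cache()
  skip_test <- alpha0 >= 1

  cols <- vector("list", length(T$functions))
  partitions <- vector("list", length(T$functions))
  for (j in seq_along(T$functions)) {
    fun <- T$functions[j]
    idx <- which(T$values[, j] == 1L)
    m <- length(idx)
    p0 <- NA_real_
    whole <- TRUE
    if (!skip_test) {
      res <- test_function_coexpression(C, idx, B = B, alpha0 = alpha0,
                                        cache = cache)
      p0 <- res$p_value
      whole <- res$is_coexpressed
    }
    if (whole) {
      subs <- list(idx)
    } else if (m == 2L) {
      subs <- list(idx[1L], idx[2L])
    } else {
      d <- 1 - C[idx, idx]
      labels <- cut_tree_by_relative_inertia(.ward_tree(d), d, L_max)
      subs <- split(idx, labels)
    }
    # order sub-clusters by decreasing size, ties by smallest gene index
    ord <- order(-lengths(subs), vapply(subs, min, numeric(1)))
    subs <- unname(subs[ord])
    partitions[[j]] <- list(fun = fun, p_value = p0,
                            coexpressed_whole = length(subs) == 1L,
                            L = length(subs),
                            sub_clusters = lapply(subs, function(s) G$genes[s]))
    block <- matrix(0L, nrow = length(G$genes), ncol = length(subs))
    for (l in seq_along(subs)) block[subs[[l]], l] <- 1L
    colnames(block) <- paste0(fun, "::", seq_along(subs))
    cols[[j]] <- block
  }
  values <- do.call(cbind, cols)
  rownames(values) <- G$genes
  col_function <- rep(T$functions, vapply(partitions, `[[`, 0L, "L"))
  col_subcluster <- unlist(lapply(partitions, function(p) seq_len(p$L)))
  out <- structure(list(values = values,
                        genes = G$genes,
                        col_function = col_function,
                        col_subcluster = col_subcluster,
                        col_margins = colSums(values),
                        row_margins = rowSums(values),
                        total = sum(values),
                        partitions = partitions,
                        alpha0 = alpha0),
                   class = "coexp_matrix")
  .check_coexp_invariants(out, T)
  out
}

# Figure-2 margin identities, asserted on every build.
.check_coexp_invariants <- function(tc, T) {
  per_fun <- tapply(tc$col_margins, factor(tc$col_function, levels = T$functions),
                    sum)
  if (!identical(as.integer(per_fun), as.integer(T$col_margins)))
    stop("internal error: sub-cluster margins do not sum to function margins")
  if (!identical(as.integer(tc$row_margins), as.integer(T$row_margins)))
    stop("internal error: row margins changed by the decomposition")
  if (tc$total != T$total)
    stop("internal error: total association count changed")
  invisible(tc)
}

#' @export
print.coexp_matrix <- function(x, ...) {
  n_split <- sum(!vapply(x$partitions, `[[`, TRUE, "coexpressed_whole"))
  cat(sprintf(paste0("coexpressed-function matrix: %d genes x %d columns ",
                     "(%d functions, %d split)\n"),
              length(x$genes), ncol(x$values), length(x$partitions), n_split))
  invisible(x)
}

#' @export
as.matrix.coexp_matrix <- function(x, ...) x$values

#' @export
dim.coexp_matrix <- function(x) dim(x$values)
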