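#' Chi-square distance between two genes' coexpressed functional profiles
#'
#' Squared chi-square distance between the row profiles of the
#' coexpressed-function matrix: each column (coexpressed biological function)
#' contributes its squared profile difference weighted by the total number of
#' associations over the column margin `card(K_l^j)`.  Two genes annotated to
#' the same function but not coexpressed fall into different sub-cluster
#' columns, so the function pushes them apart instead of pulling them
#' together.
#'
#' @param tc a `coexp_matrix` from [build_t_coexp()] (an
#'   `annotation_matrix` works too, giving the plain chi-square distance on
#'   `T`).
#' @param k,kp gene identifiers or indices; both must be annotated.
#' @return non-negative squared distance.
#' @export
chi2_distance <- function(tc, k, kp) {
  X <- .binary_values(tc)
  i <- if (is.character(k)) match(k, rownames(X)) else as.integer(k)
  j <- if (is.character(kp)) match(kp, rownames(X)) else as.integer(kp)
  if (anyNA(c(i, j))) stop("unknown gene identifier")
  rm <- rowSums(X)
  for (g in c(i, j)) if (rm[g] == 0)
    stop("gene '", rownames(X)[g], "' has no annotation; ",
         "chi-square profiles are undefined for it")
  w <- sum(X) / colSums(X)
  diff <- X[i, ] / rm[i] - X[j, ] / rm[j]
  sum(w * diff^2)
}

.binary_values <- function(x) {
  if (inherits(x, "coexp_matrix") || inherits(x, "annotation_matrix"))
    x$values
  else if (is.matrix(x)) x
  else stop("expected a coexp_matrix, annotation_matrix or binary matrix")
}

#' All-pairs chi-square distance matrix between genes
#'
#' Applies [chi2_distance()] to every gene pair through one weighted
#' cross-product.  Entries are the squared chi-square distances (the sum in
#' the distance definition, no radical); they equal squared Euclidean
#' distances between the genes' correspondence-analysis row coordinates when
#' all components are kept (see [ca_row_coordinates()]).
#'
#' @param tc a `coexp_matrix` (or `annotation_matrix`).
#' @return object of class `gene_dist`: list with `values` (symmetric
#'   squared-distance matrix, zero diagonal), `genes`, and
#'   `is_squared = TRUE`.
#' @export
coexp_distance <- function(tc) {
  X <- .binary_values(tc)
  rm <- rowSums(X)
  if (any(rm == 0))
    stop("unannotated gene(s): ",
         paste(utils::head(rownames(X)[rm == 0], 10L), collapse = ", "))
  w <- sum(X) / colSums(X)
  P <- sweep(X / rm, 2L, sqrt(w), `*`)
  cross <- tcrossprod(P)
  q <- diag(cross)
  D <- outer(q, q, `+`) - 2 * cross
  D[D < 0] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  structure(list(values = D, genes = rownames(X), is_squared = TRUE),
            class = "gene_dist")
}

#' @export
print.gene_dist <- function(x, ...) {
  cat(sprintf("gene distance matrix: %d genes (%s)\n", length(x$genes),
              if (x$is_squared) "squared chi-square" else "chi-square"))
  invisible(x)
}

#' @export
as.matrix.gene_dist <- function(x, ...) x$values

#' Correspondence-analysis row coordinates of a binary annotation matrix
#'
#' Row principal coordinates from the generalized SVD of the standardized
#' residuals; squared Euclidean distances between rows equal the chi-square
#' distances returned by [coexp_distance()].  This embedding realizes the
#' chi-square metric as an ordinary Euclidean geometry, which is what
#' K-means requires.
#'
#' @param tc a `coexp_matrix` or `annotation_matrix`.
#' @param tol singular values below `tol * max(sv)` are dropped.
#' @return numeric matrix of row coordinates (genes x components).
#' @export
ca_row_coordinates <- function(tc, tol = 1e-10) {
  X <- .binary_values(tc)
  n <- sum(X)
  P <- X / n
  r <- rowSums(P)
  cc <- colSums(P)
  if (any(r == 0)) stop("unannotated gene(s); cannot embed")
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  keep <- sv$d > tol * max(sv$d)
  F <- sweep(sv$u[, keep, drop = FALSE], 2L, sv$d[keep], `*`) / sqrt(r)
  rownames(F) <- rownames(X)
  F
}

#' Construct a gene partition object
#'
#' @param labels named integer (or coercible) vector of cluster labels, one
#'   per gene.
#' @return object of class `gene_partition`: list with `genes`, `labels`
#'   (integer, renumbered 1..n_clusters), `clusters` (list of gene-ID sets)
#'   and `n_clusters`.
#' @export
gene_partition <- function(labels) {
  if (is.null(names(labels))) stop("'labels' must be named by gene")
  lab <- as.integer(factor(labels, levels = unique(labels)))
  names(lab) <- names(labels)
  clusters <- split(names(lab), lab)
  structure(list(genes = names(lab), labels = lab,
                 clusters = unname(clusters),
                 n_clusters = length(clusters)),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("gene partition: %d genes in %d clusters (%d singletons)\n",
              length(x$genes), x$n_clusters, sum(sizes == 1L)))
  invisible(x)
}

#' Cluster genes from the integrated distance matrix
#'
#' `method = "hac"` applies Ward-linkage hierarchical ascending
#' classification to the (square-rooted) chi-square distances and cuts the
#' tree at `n_clusters`.  `method = "kmeans"` runs K-means in a Euclidean
#' embedding of the metric (classical MDS of the square-rooted distances,
#' which for the chi-square distance coincides with the CA row-coordinate
#' space) with multiple restarts, keeping the best inertia.  Singleton
#' clusters are permitted.
#'
#' @param D a `gene_dist` from [coexp_distance()] (or any symmetric squared
#'   distance matrix with gene rownames).
#' @param n_clusters number of clusters (2..number of genes).
#' @param method `"hac"` (default) or `"kmeans"`.
#' @param nstart K-means restarts.
#' @param seed optional seed for the K-means restarts.
#' @return a [gene_partition].
#' @export
cluster_genes <- function(D, n_clusters, method = c("hac", "kmeans"),
                          nstart = 20L, seed = NULL) {
  method <- match.arg(method)
  values <- if (inherits(D, "gene_dist")) D$values else D
  genes <- rownames(values)
  n <- nrow(values)
  if (n_clusters < 2L || n_clusters > n)
    stop("'n_clusters' must be between 2 and the number of genes")
  if (n_clusters == n) {
    return(gene_partition(stats::setNames(seq_len(n), genes)))
  }
  if (method == "hac") {
    tree <- stats::hclust(stats::as.dist(sqrt(values)), method = "ward.D2")
    labels <- stats::cutree(tree, n_clusters)
  } else {
    if (!is.null(seed)) set.seed(seed)
    # the embedding dimension is bounded by the matrix rank; trailing zero
    # eigenvalues are expected and harmless
    mds <- suppressWarnings(
      stats::cmdscale(sqrt(values), k = min(n - 1L, 60L), eig = TRUE))
    keep <- mds$eig[seq_len(ncol(mds$points))] > 1e-9 * max(mds$eig)
    coords <- mds$points[, keep, drop = FALSE]
    km <- stats::kmeans(coords, centers = n_clusters, nstart = nstart,
                        iter.max = 50L)
    labels <- km$cluster
  }
  gene_partition(stats::setNames(labels, genes))
}
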