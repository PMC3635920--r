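#' Run the full integrated clustering pipeline
#'
#' Encode annotations, decompose biological functions into coexpressed
#' biological functions, compute the chi-square distance, cluster the genes
#' and evaluate the partition.  Gene universes are reconciled by
#' intersection (dropped genes are counted in a message); genes without any
#' annotation after function filtering are excluded from the distance and
#' the partition, since their chi-square profiles are undefined.
#'
#' @param expression an [expression_matrix] or a path readable by
#'   [read_expression()].
#' @param annotations an [annotation_matrix][build_annotation_matrix], a
#'   two-column association data frame, or a path readable by
#'   [read_associations()].
#' @param n_clusters number of gene clusters (required; no automatic
#'   selection).
#' @param method clustering algorithm: `"hac"` or `"kmeans"`.
#' @param obo optional term-parent DAG (named list from [read_obo()] or a
#'   path); when given, associations are propagated to ancestors first.
#' @param min_genes minimum genes per function (see [filter_functions()]).
#' @param alpha0 coexpression threshold of the decomposition's filtering
#'   step.
#' @param B permutations for the filtering step and the evaluation.
#' @param alpha evaluation significance threshold.
#' @param seed top-level seed fanned out to the decomposition, clustering
#'   and evaluation.
#' @param out_dir optional directory; when given, the partition, the
#'   per-cluster evaluation, the summary and a manifest (all parameters,
#'   seed, package version) are written there.
#' @return invisible list with `t_coexp`, `distance`, `partition`,
#'   `evaluation`, and `manifest`.
#' @export
run_full_pipeline <- function(expression, annotations, n_clusters,
                              method = "hac", obo = NULL, min_genes = 2L,
                              alpha0 = 0.10, B = 500L, alpha = 0.05,
                              seed = 1L, out_dir = NULL) {
  G <- if (inherits(expression, "expression_matrix")) expression
       else read_expression(expression)
  assoc <- NULL
  if (inherits(annotations, "annotation_matrix")) {
    T <- annotations
  } else {
    assoc <- if (is.character(annotations)) read_associations(annotations)
             else .as_association_frame(annotations)
    if (!is.null(obo)) {
      dag <- if (is.character(obo)) read_obo(obo) else obo
      assoc <- propagate_ancestors(assoc, dag)
    }
    common0 <- intersect(unique(assoc$gene), G$genes)
    if (length(common0) == 0L)
      stop("expression and annotation gene universes do not intersect")
    assoc <- assoc[assoc$gene %in% common0, , drop = FALSE]
    T <- build_annotation_matrix(assoc, G$genes)
  }
  common <- intersect(G$genes, T$genes)
  if (length(common) == 0L)
    stop("expression and annotation gene universes do not intersect")
  dropped <- (length(G$genes) - length(common)) +
             (length(T$genes) - length(common))
  if (dropped > 0L)
    message(dropped, " gene entr(ies) outside the common universe dropped")
  G <- expression_matrix(G$values[common, , drop = FALSE])
  T <- .annotation_matrix(T$values[common, , drop = FALSE])
  T <- filter_functions(T, min_genes)
  if (any(T$unannotated)) {
    message(sum(T$unannotated), " unannotated gene(s) excluded from clustering")
    keep <- !T$unannotated
    G <- expression_matrix(G$values[keep, , drop = FALSE])
    T <- .annotation_matrix(T$values[keep, , drop = FALSE])
    T <- filter_functions(T, min_genes)
  }
  seeds <- .derive_seeds(seed, 3L)
  tc <- build_t_coexp(G, T, alpha0 = alpha0, B = B, seed = seeds[[1L]])
  D <- coexp_distance(tc)
  partition <- cluster_genes(D, n_clusters, method = method,
                             seed = seeds[[2L]])
  evaluation <- evaluate_partition(G, T, partition, B = B, alpha = alpha,
                                   seed = seeds[[3L]])
  manifest <- list(package = "coexgo",
                   version = as.character(utils::packageVersion("coexgo")),
                   n_genes = length(G$genes), n_samples = G$I,
                   n_functions = length(T$functions),
                   n_coexp_columns = ncol(tc$values),
                   n_clusters = n_clusters, method = method,
                   min_genes = min_genes, alpha0 = alpha0, B = B,
                   alpha = alpha, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_partition(partition, file.path(out_dir, "partition.tsv"))
    write_evaluation(evaluation, file.path(out_dir, "cluster_evaluation.tsv"))
    write_t_coexp(tc, report_path = file.path(out_dir, "decomposition.tsv"))
    jsonlite::write_json(as.list(evaluation$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(t_coexp = tc, distance = D, partition = partition,
                 evaluation = evaluation, manifest = manifest))
}
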