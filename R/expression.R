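#' Construct a validated gene x sample expression matrix
#'
#' @param values numeric matrix, genes as rows (rownames = gene IDs) and
#'   samples as columns.  Missing values and constant-expression genes are
#'   rejected; gene IDs must be unique.
#' @return object of class `expression_matrix`: list with `values`, `genes`,
#'   `samples`, `I` (number of samples).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant expression for gene(s): ",
         paste(utils::head(rownames(values)[sds == 0], 10L), collapse = ", "))
  structure(list(values = values, genes = rownames(values),
                 samples = colnames(values), I = ncol(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples\n",
              length(x$genes), x$I))
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene-gene Pearson correlation matrix
#'
#' @param G an [expression_matrix].
#' @return symmetric correlation matrix over genes.
#' @export
gene_correlation <- function(G) {
  stopifnot(inherits(G, "expression_matrix"))
  stats::cor(t(G$values))
}

#' Correlation distance between genes
#'
#' Distance `d(k, k') = 1 - r(k, k')` where `r` is the Pearson correlation
#' of the two genes' expression profiles across samples (standardising by
#' the per-gene mean and standard deviation; the 1/I population
#' normalisation cancels in the correlation ratio).  Values lie in
#' `[0, 2]` with a zero diagonal.
#'
#' @param G an [expression_matrix].
#' @param genes optional character or integer subset (>= 2 genes).
#' @return symmetric distance matrix.
#' @export
correlation_distance <- function(G, genes = NULL) {
  stopifnot(inherits(G, "expression_matrix"))
  values <- G$values
  if (!is.null(genes)) {
    values <- values[genes, , drop = FALSE]
    if (nrow(values) < 2L) stop("need at least 2 genes")
    sds <- apply(values, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant expression for gene(s): ",
           paste(rownames(values)[sds == 0], collapse = ", "))
  }
  if (ncol(values) < 3L) stop("need at least 3 samples")
  d <- 1 - stats::cor(t(values))
  diag(d) <- 0
  d
}
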