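#' Build the binary gene x biological-function annotation matrix
#'
#' Encodes gene/term associations as a binary matrix `T` whose rows are gene
#' functional profiles and whose columns are biological functions (gene sets).
#' Row margins count the functions a gene carries, column margins the genes a
#' function carries, and the total counts all associations.
#'
#' @param associations two-column data frame (or matrix) of gene, function
#'   pairs; duplicated pairs collapse to a single association.
#' @param gene_universe ordered character vector of gene identifiers defining
#'   the rows of the matrix; every association's gene must belong to it.
#' @return An object of class `annotation_matrix`: a list with elements
#'   `values` (binary integer matrix), `genes`, `functions`, `row_margins`,
#'   `col_margins`, `total`, and `unannotated` (logical flag per gene marking
#'   all-zero rows, which downstream distances exclude).
#' @examples
#' pairs <- data.frame(gene = c("g1", "g1", "g2"), term = c("f1", "f2", "f1"))
#' T <- build_annotation_matrix(pairs, c("g1", "g2"))
#' T$total  # 3
#' @export
build_annotation_matrix <- function(associations, gene_universe) {
  if (length(gene_universe) == 0L)
    stop("'gene_universe' must be non-empty")
  gene_universe <- as.character(gene_universe)
  if (anyDuplicated(gene_universe))
    stop("duplicated gene identifiers in 'gene_universe': ",
         paste(unique(gene_universe[duplicated(gene_universe)]), collapse = ", "))
  associations <- .as_association_frame(associations)
  if (nrow(associations) == 0L)
    stop("empty association list: nothing to encode")
  unknown <- setdiff(unique(associations$gene), gene_universe)
  if (length(unknown))
    stop("association references gene(s) outside the universe: ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  funs <- unique(associations$term)
  values <- matrix(0L, nrow = length(gene_universe), ncol = length(funs),
                   dimnames = list(gene_universe, funs))
  values[cbind(match(associations$gene, gene_universe),
               match(associations$term, funs))] <- 1L
  .annotation_matrix(values)
}

.as_association_frame <- function(associations) {
  if (is.matrix(associations)) associations <- as.data.frame(associations)
  if (!is.data.frame(associations) || ncol(associations) < 2L)
    stop("'associations' must have two columns: gene, function")
  out <- data.frame(gene = as.character(associations[[1L]]),
                    term = as.character(associations[[2L]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

# Internal constructor: recomputes margins from the values.
.annotation_matrix <- function(values) {
  storage.mode(values) <- "integer"
  if (any(values != 0L & values != 1L))
    stop("annotation matrix entries must be 0 or 1")
  row_margins <- rowSums(values)
  col_margins <- colSums(values)
  structure(list(values = values,
                 genes = rownames(values),
                 functions = colnames(values),
                 row_margins = row_margins,
                 col_margins = col_margins,
                 total = sum(values),
                 unannotated = row_margins == 0L),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation matrix: %d genes x %d functions, %d associations\n",
              length(x$genes), length(x$functions), x$total))
  if (any(x$unannotated))
    cat(sprintf("  %d gene(s) without annotation (flagged)\n",
                sum(x$unannotated)))
  invisible(x)
}

#' @export
as.matrix.annotation_matrix <- function(x, ...) x$values

#' @export
dim.annotation_matrix <- function(x) dim(x$values)

#' Propagate gene/term associations to term ancestors
#'
#' Augments each gene's annotations with the transitive ancestor closure of
#' its terms in a term-parent DAG (e.g. GO `is_a` edges), so that annotating
#' a gene to a term also annotates it to every ancestor of the term.  The
#' operation is idempotent.  Terms absent from the DAG are passed through
#' unchanged and reported via a message.
#'
#' @param associations two-column data frame of gene, term pairs.
#' @param dag named list mapping a term to the character vector of its direct
#'   parents; must be acyclic.
#' @return augmented, de-duplicated association data frame.
#' @export
propagate_ancestors <- function(associations, dag) {
  associations <- .as_association_frame(associations)
  if (length(dag) == 0L) return(associations)
  closure <- .ancestor_closure(dag)
  known <- names(closure)
  missing_terms <- setdiff(unique(associations$term), known)
  if (length(missing_terms))
    message(length(missing_terms),
            " term(s) absent from the DAG kept as-is: ",
            paste(utils::head(missing_terms, 5L), collapse = ", "))
  extra <- lapply(seq_len(nrow(associations)), function(i) {
    anc <- closure[[associations$term[i]]]
    if (is.null(anc) || !length(anc)) return(NULL)
    data.frame(gene = associations$gene[i], term = anc,
               stringsAsFactors = FALSE)
  })
  unique(rbind(associations, do.call(rbind, extra)))
}

# Transitive ancestors per term with cycle detection (DFS, three colours).
.ancestor_closure <- function(dag) {
  terms <- union(names(dag), unlist(dag, use.names = FALSE))
  state <- new.env(parent = emptyenv())   # 1 = on stack, 2 = done
  closure <- new.env(parent = emptyenv())
  visit <- function(t) {
    s <- get0(t, envir = state, inherits = FALSE)
    if (identical(s, 2L)) return(get(t, envir = closure))
    if (identical(s, 1L)) stop("cycle detected in the term DAG at '", t, "'")
    assign(t, 1L, envir = state)
    parents <- dag[[t]]
    anc <- character(0)
    for (p in parents) anc <- union(anc, union(p, visit(p)))
    assign(t, anc, envir = closure)
    assign(t, 2L, envir = state)
    anc
  }
  res <- lapply(terms, visit)
  names(res) <- terms
  res
}

#' Drop sparsely annotated functions
#'
#' Removes columns annotating fewer than `min_genes` genes and recomputes all
#' margins.  A function with a single gene carries no between-gene similarity
#' and cannot be decomposed, so the default removes singletons.
#'
#' @param T an [annotation_matrix][build_annotation_matrix].
#' @param min_genes minimum column margin to keep (>= 1).
#' @return filtered `annotation_matrix` over the same gene universe.
#' @export
filter_functions <- function(T, min_genes = 2L) {
  stopifnot(inherits(T, "annotation_matrix"), min_genes >= 1L)
  keep <- T$col_margins >= min_genes
  if (!any(keep))
    stop("no function annotates at least ", min_genes,
         " genes; lower 'min_genes'")
  .annotation_matrix(T$values[, keep, drop = FALSE])
}
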