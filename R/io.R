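# Readers and writers for the plain-text interchange formats.

#' Read gene/term associations from two-column delimited text
#'
#' @param path file with one gene<sep>term pair per line, no header.
#' @param sep field separator (default tab).
#' @return data frame with columns `gene`, `term`.
#' @export
read_associations <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L)
    stop("expected two columns (gene, term) in ", path)
  .as_association_frame(df[, 1:2])
}

#' Read gene/term associations from a GAF 2.x file
#'
#' Uses column 2 (DB object symbol) and column 5 (GO ID); lines starting with
#' `!` are comments.  Evidence codes (column 7) can be excluded, e.g.
#' `exclude_evidence = "IEA"`.
#'
#' @param path GAF file path.
#' @param exclude_evidence character vector of evidence codes to drop
#'   (default none).
#' @return data frame with columns `gene`, `term`.
#' @export
read_gaf <- function(path, exclude_evidence = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "!", colClasses = "character",
                          fill = TRUE)
  if (ncol(df) < 7L)
    stop("not a GAF file (fewer than 7 tab-separated columns): ", path)
  if (length(exclude_evidence))
    df <- df[!(df[[7L]] %in% exclude_evidence), , drop = FALSE]
  if (nrow(df) == 0L) stop("no associations left after evidence filtering")
  .as_association_frame(df[, c(2L, 5L)])
}

#' Read a term-parent DAG from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas, collecting `is_a` edges and optionally
#' `relationship: part_of` edges.
#'
#' @param path OBO file path.
#' @param relationships edge types to keep: subset of
#'   `c("is_a", "part_of")`; default `is_a` only.
#' @return named list mapping each term ID to its direct parents.
#' @export
read_obo <- function(path, relationships = "is_a") {
  relationships <- match.arg(relationships, c("is_a", "part_of"),
                             several.ok = TRUE)
  lines <- readLines(path, warn = FALSE)
  dag <- list()
  id <- NULL
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; id <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:") && "is_a" %in% relationships) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (!is.null(id)) dag[[id]] <- union(dag[[id]], parent)
    } else if (startsWith(ln, "relationship:") &&
               "part_of" %in% relationships) {
      rest <- trimws(sub("^relationship:", "", ln))
      if (startsWith(rest, "part_of")) {
        parent <- trimws(sub("!.*$", "", sub("^part_of", "", rest)))
        if (!is.null(id)) dag[[id]] <- union(dag[[id]], parent)
      }
    }
  }
  dag
}

#' Write an annotation matrix as delimited text
#'
#' First column is the gene ID, remaining columns the binary associations
#' with a header row of function IDs.
#'
#' @param T an `annotation_matrix` or `coexp_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_annotation_matrix <- function(T, path, sep = "\t") {
  values <- if (inherits(T, "coexp_matrix")) T$values else as.matrix(T)
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from delimited text
#'
#' Expects a header row of sample IDs and gene IDs in the first column.
#' Validation rejects non-numeric cells (reported with row and column),
#' missing values (no imputation), constant-expression genes (named), and
#' duplicated gene IDs whose rows conflict; duplicated IDs with identical
#' rows are collapsed.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return an [expression_matrix].
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("expected gene IDs plus at least one sample column")
  genes <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(genes, colnames(raw))))
  bad <- which(is.na(values) & !is.na(raw) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 raw[bad[1L, , drop = FALSE]], genes[bad[1L, 1L]],
                 colnames(values)[bad[1L, 2L]]))
  if (anyNA(values)) {
    miss <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("missing value at gene '%s', sample '%s' (no imputation)",
                 genes[miss[1L, 1L]], colnames(values)[miss[1L, 2L]]))
  }
  if (anyDuplicated(genes)) {
    for (g in unique(genes[duplicated(genes)])) {
      rows <- values[genes == g, , drop = FALSE]
      if (nrow(unique(rows)) > 1L)
        stop("duplicated gene ID '", g, "' with conflicting expression rows")
    }
    keep <- !duplicated(genes)
    values <- values[keep, , drop = FALSE]
  }
  expression_matrix(values)
}

#' Write a gene partition as two-column delimited text
#'
#' @param partition a [gene_partition].
#' @param path output path.
#' @param sep field separator.
#' @export
write_partition <- function(partition, path, sep = "\t") {
  stopifnot(inherits(partition, "gene_partition"))
  utils::write.table(data.frame(gene = partition$genes,
                                cluster = partition$labels),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene partition written by [write_partition()]
#' @param path file path.
#' @param sep field separator.
#' @return a [gene_partition].
#' @export
read_partition <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = c("character", "integer"))
  gene_partition(stats::setNames(df$cluster, df$gene))
}

#' Write the coexpressed-function matrix and its partition report
#'
#' The matrix is written with composite `function::l` column headers; the
#' report lists, per function, the number of sub-clusters, the coexpression
#' p-value from the filtering step, and the member genes of each sub-cluster.
#'
#' @param tc a `coexp_matrix` from [build_t_coexp()].
#' @param matrix_path,report_path output paths (either may be `NULL` to skip).
#' @param sep field separator.
#' @export
write_t_coexp <- function(tc, matrix_path = NULL, report_path = NULL,
                          sep = "\t") {
  stopifnot(inherits(tc, "coexp_matrix"))
  if (!is.null(matrix_path)) write_annotation_matrix(tc, matrix_path, sep)
  if (!is.null(report_path)) {
    rows <- lapply(tc$partitions, function(p) {
      data.frame(fun = p$fun, L = p$L,
                 p_value = ifelse(is.na(p$p_value), NA, p$p_value),
                 coexpressed_whole = p$coexpressed_whole,
                 subcluster = seq_along(p$sub_clusters),
                 genes = vapply(p$sub_clusters, paste, "", collapse = ","),
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows), report_path, sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(tc)
}
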