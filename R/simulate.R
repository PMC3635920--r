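#' Configuration of the paired expression/annotation simulator
#'
#' @param I number of samples.
#' @param K number of genes.
#' @param n_blocks number of planted coexpression blocks (clusters of
#'   coexpressed genes).
#' @param rho_within within-block population correlation.
#' @param rho_between between-block population correlation (default 0).
#' @param r intensity of randomness: number of row-permuted random copies of
#'   the structured annotation matrix (positive integer).
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(I = 10L, K = 300L, n_blocks = 20L,
                              rho_within = 0.85, rho_between = 0,
                              r = 1L, seed = 1L) {
  stopifnot(I >= 3L, K >= n_blocks, n_blocks >= 1L,
            rho_between >= 0, rho_between <= rho_within, rho_within <= 1,
            r >= 1L)
  structure(list(I = as.integer(I), K = as.integer(K),
                 n_blocks = as.integer(n_blocks),
                 rho_within = rho_within, rho_between = rho_between,
                 r = as.integer(r), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate block-correlated Gaussian expression data
#'
#' Draws a gene x sample matrix from a multivariate Gaussian whose
#' population correlation is block-diagonal: `rho_within` inside each
#' planted block of coexpressed genes and `rho_between` elsewhere (factor
#' construction: a shared global factor, one factor per block, and
#' independent noise).  Block sizes are as equal as `K/n_blocks` allows.
#'
#' @param config a [simulation_config] (its `seed` is used unless the
#'   calling context has already seeded the RNG and `use_seed = FALSE`).
#' @param use_seed set the RNG from `config$seed` (default `TRUE`).
#' @return list with `G` (an [expression_matrix]) and `block_truth`
#'   (integer planted-block label per gene).
#' @export
simulate_expression <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (use_seed) set.seed(config$seed)
  K <- config$K; I <- config$I; nb <- config$n_blocks
  sizes <- rep(K %/% nb, nb)
  extra <- K %% nb
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block_truth <- rep(seq_len(nb), sizes)
  rb <- config$rho_between; rw <- config$rho_within
  global <- matrix(stats::rnorm(I), nrow = 1L)
  block_factors <- matrix(stats::rnorm(nb * I), nrow = nb)
  noise <- matrix(stats::rnorm(K * I), nrow = K)
  values <- sqrt(rb) * global[rep(1L, K), , drop = FALSE] +
    sqrt(rw - rb) * block_factors[block_truth, , drop = FALSE] +
    sqrt(1 - rw) * noise
  dimnames(values) <- list(sprintf("gene%03d", seq_len(K)),
                           sprintf("sample%02d", seq_len(I)))
  list(G = expression_matrix(values), block_truth = block_truth)
}

#' Structured annotations from the expression classification tree
#'
#' Emulates annotations that carry the experiment's signal: genes are
#' clustered hierarchically on the correlation distance of their expression
#' profiles only, and every internal node of the tree except the root
#' becomes one biological function annotating exactly the genes below it.
#' Genes with similar expression profiles therefore mechanically share close
#' functional profiles, and the columns mimic the nested structure of the GO
#' hierarchy (any two are nested or disjoint).
#'
#' @param G an [expression_matrix] with at least 3 genes.
#' @return an [annotation_matrix][build_annotation_matrix] with `K - 2`
#'   columns for a binary tree over `K` genes.
#' @export
simulate_structured_annotations <- function(G) {
  stopifnot(inherits(G, "expression_matrix"))
  K <- length(G$genes)
  if (K < 3L) stop("need at least 3 genes to build a classification tree")
  d <- correlation_distance(G)
  tree <- .ward_tree(d)
  # leaves under each merge node; the last merge is the root and is skipped
  members <- vector("list", K - 1L)
  for (i in seq_len(K - 1L)) {
    left <- tree$merge[i, 1L]; right <- tree$merge[i, 2L]
    members[[i]] <- c(if (left < 0L) -left else members[[left]],
                      if (right < 0L) -right else members[[right]])
  }
  nodes <- members[seq_len(K - 2L)]
  values <- matrix(0L, nrow = K, ncol = length(nodes),
                   dimnames = list(G$genes,
                                   sprintf("node%03d", seq_along(nodes))))
  for (j in seq_along(nodes)) values[nodes[[j]], j] <- 1L
  .annotation_matrix(values)
}

#' Random annotations preserving function margins
#'
#' Juxtaposes `r` copies of the structured annotation matrix and
#' independently permutes the rows within each column, producing functions
#' unrelated to expression whose column margins (the functions' degrees of
#' specificity) are conserved exactly.  Row margins are not preserved in
#' general.
#'
#' @param T_e structured [annotation_matrix][build_annotation_matrix].
#' @param r number of permuted copies (>= 1).
#' @return an `annotation_matrix` with `r * ncol(T_e)` columns named
#'   `rand<copy>_<source>`.
#' @export
simulate_random_annotations <- function(T_e, r = 1L) {
  stopifnot(inherits(T_e, "annotation_matrix"), r >= 1L)
  K <- length(T_e$genes)
  J <- length(T_e$functions)
  cols <- vector("list", r)
  for (copy in seq_len(r)) {
    block <- apply(T_e$values, 2L, function(col) col[sample.int(K)])
    colnames(block) <- sprintf("rand%d_%s", copy, T_e$functions)
    cols[[copy]] <- block
  }
  values <- do.call(cbind, cols)
  rownames(values) <- T_e$genes
  .annotation_matrix(values)
}

#' Simulate a paired expression + annotation dataset
#'
#' Assembles the full benchmark generator: block-correlated expression,
#' structured annotations derived from the expression classification tree,
#' and `r` times as many margin-preserving random annotations, juxtaposed
#' into one annotation matrix with per-column provenance tags.
#'
#' @param config a [simulation_config].
#' @return object of class `simulated_dataset`: list with `G`
#'   ([expression_matrix]), `T` (combined
#'   [annotation_matrix][build_annotation_matrix]), `block_truth`,
#'   `column_provenance` (`"structured"`/`"random"` per column), and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  expr <- simulate_expression(config, use_seed = FALSE)
  T_e <- simulate_structured_annotations(expr$G)
  T_r <- simulate_random_annotations(T_e, config$r)
  values <- cbind(T_e$values, T_r$values)
  T_sim <- .annotation_matrix(values)
  provenance <- c(rep("structured", ncol(T_e$values)),
                  rep("random", ncol(T_r$values)))
  structure(list(G = expr$G, T = T_sim, block_truth = expr$block_truth,
                 column_provenance = provenance, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("simulated dataset: %d genes x %d samples, ",
                     "%d structured + %d random functions (r = %d)\n"),
              length(x$G$genes), x$G$I,
              sum(x$column_provenance == "structured"),
              sum(x$column_provenance == "random"), x$config$r))
  invisible(x)
}
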