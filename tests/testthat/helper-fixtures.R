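# Fixtures built in code: planted-block expression data, toy annotation
# matrices, and independent oracles for the chi-square distance and the
# homogeneity indicator.

# Expression matrix with planted coexpression blocks: each block shares a
# base profile plus independent noise.
make_block_expression <- function(n_blocks = 3L, block_size = 5L, I = 10L,
                                  noise = 0.15, anti = FALSE, seed = 1L) {
  set.seed(seed)
  profs <- lapply(seq_len(n_blocks), function(b) stats::rnorm(I))
  if (anti && n_blocks == 2L) profs[[2L]] <- -profs[[1L]]
  values <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    t(replicate(block_size, profs[[b]] + stats::rnorm(I, 0, noise)))
  }))
  rownames(values) <- sprintf("g%02d", seq_len(n_blocks * block_size))
  colnames(values) <- sprintf("s%02d", seq_len(I))
  list(G = expression_matrix(values),
       blocks = rep(seq_len(n_blocks), each = block_size))
}

# Random binary annotation matrix with no empty rows or columns.
make_random_annotation <- function(K = 12L, J = 7L, p = 0.4, seed = 1L) {
  set.seed(seed)
  repeat {
    X <- matrix(stats::rbinom(K * J, 1L, p), K, J)
    if (all(rowSums(X) > 0) && all(colSums(X) > 0)) break
  }
  dimnames(X) <- list(sprintf("g%02d", seq_len(K)),
                      sprintf("f%02d", seq_len(J)))
  coexgo:::.annotation_matrix(X)
}

# Independent oracle for the squared chi-square distance: explicit
# term-by-term double sum over functions and sub-clusters (columns), kept
# separate from the package's cross-product path.
chi2_oracle <- function(X, i, j) {
  total <- sum(X)
  rm <- unname(rowSums(X))
  acc <- 0
  for (cc in seq_len(ncol(X))) {
    w <- total / sum(X[, cc])
    acc <- acc + w * (X[i, cc] / rm[i] - X[j, cc] / rm[j])^2
  }
  acc
}

# Independent oracle for the homogeneity indicator: build the cluster's
# subtable, drop empty columns, and evaluate the chi-square discrepancy
# cell by cell.
bhi_oracle <- function(X, idx) {
  sub <- X[idx, , drop = FALSE]
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  n <- sum(sub)
  E <- outer(rowSums(sub), colSums(sub)) / n
  chi2 <- sum((sub - E)^2 / E)
  1 - chi2 / (n * (length(idx) - 1))
}

# Small simulated paired dataset for integration tests.
make_small_dataset <- function(seed = 5L, K = 60L, n_blocks = 4L, r = 1L) {
  simulate_dataset(simulation_config(I = 10L, K = K, n_blocks = n_blocks,
                                     r = r, seed = seed))
}
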