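# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean of the off-diagonal entries of a symmetric matrix with unit diagonal
# (used for the coexpression indicator: diag(cor) == 1 exactly).
.offdiag_mean <- function(S) {
  m <- nrow(S)
  (sum(S) - sum(diag(S))) / (m * (m - 1))
}

# Environment-backed cache for permutation null distributions.  The null law
# of either indicator depends only on the data matrix and the cluster size,
# so within one call draws can be shared across same-sized clusters.
.new_null_cache <- function() new.env(parent = emptyenv())

.cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  get0(key, envir = cache, inherits = FALSE)
}

.cache_set <- function(cache, key, value) {
  if (!is.null(cache)) assign(key, value, envir = cache)
  invisible(value)
}

# B null values of the coexpression indicator for random size-m gene sets
# drawn without replacement from the K genes of the correlation matrix C.
# For large m the B quadratic forms are batched through one matrix product.
.ci_null_values <- function(C, size, B, cache = NULL) {
  key <- sprintf("ci.%d.%d", size, B)
  hit <- .cache_get(cache, key)
  if (!is.null(hit)) return(hit)
  K <- nrow(C)
  denom <- size * (size - 1)
  if (size >= 25L) {
    M <- matrix(0, nrow = B, ncol = K)
    for (b in seq_len(B)) M[b, sample.int(K, size)] <- 1
    vals <- (rowSums((M %*% C) * M) - size) / denom
  } else {
    vals <- vapply(seq_len(B), function(b) {
      idx <- sample.int(K, size)
      (sum(C[idx, idx]) - size) / denom
    }, numeric(1))
  }
  .cache_set(cache, key, vals)
}

# Proportion of null values strictly exceeding the observed value.
.perm_pvalue <- function(observed, null_values) {
  mean(null_values > observed)
}

# Ward tree on a squared-distance-like matrix d (Eq.-1 correlation distances
# behave as squared Euclidean distances between standardised profiles, so
# ward.D2 is applied to sqrt(d)).
.ward_tree <- function(d) {
  stats::hclust(stats::as.dist(sqrt(pmax(d, 0))), method = "ward.D2")
}

# Total within-cluster inertia of a labelled partition under squared
# distances d: sum over clusters of (sum of within-pair d) / (2 * size).
.partition_inertia <- function(d, labels) {
  tot <- 0
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) > 1L) tot <- tot + sum(d[idx, idx]) / (2 * length(idx))
  }
  tot
}

# Derive independent sub-stream seeds from one top-level seed (kept < 2^31).
.derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
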