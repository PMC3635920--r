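test_that("simulated expression has the configured block structure", {
  cfg <- simulation_config(I = 200L, K = 60L, n_blocks = 4L,
                           rho_within = 0.85, seed = 17L)
  sim <- simulate_expression(cfg)
  expect_identical(dim(sim$G$values), c(60L, 200L))
  expect_identical(as.integer(table(sim$block_truth)), rep(15L, 4L))
  C <- gene_correlation(sim$G)
  same <- outer(sim$block_truth, sim$block_truth, `==`)
  diag(same) <- NA
  within <- mean(C[which(same)])
  between <- mean(C[which(!same)])
  expect_lt(abs(within - 0.85), 0.05)
  expect_lt(abs(between), 0.05)
})

test_that("zero within-block correlation gives independent genes", {
  cfg <- simulation_config(I = 150L, K = 40L, n_blocks = 4L,
                           rho_within = 0, seed = 18L)
  sim <- simulate_expression(cfg)
  C <- gene_correlation(sim$G)
  expect_lt(abs(mean(C[upper.tri(C)])), 0.03)
})

test_that("structured annotations are the non-root tree nodes", {
  cfg <- simulation_config(I = 20L, K = 30L, n_blocks = 3L, seed = 19L)
  sim <- simulate_expression(cfg)
  T_e <- simulate_structured_annotations(sim$G)
  # binary tree over K leaves: K - 1 internal nodes, root excluded
  expect_identical(ncol(T_e$values), 30L - 2L)
  # column margin equals the number of leaves under the node
  expect_true(all(T_e$col_margins >= 2))
  expect_true(all(T_e$col_margins < 30))
  # hierarchical nesting: any two columns are nested or disjoint
  X <- T_e$values
  for (a in seq_len(ncol(X) - 1L)) for (b in (a + 1L):ncol(X)) {
    overlap <- sum(X[, a] & X[, b])
    expect_true(overlap == 0 || overlap == min(sum(X[, a]), sum(X[, b])))
  }
  # coexpressed genes mechanically share close functional profiles:
  # profile similarity is higher within planted blocks than between
  jacc <- function(a, b) sum(a & b) / sum(a | b)
  same <- outer(sim$block_truth, sim$block_truth, `==`)
  pairs <- which(upper.tri(same), arr.ind = TRUE)
  sims <- apply(pairs, 1L, function(p) jacc(X[p[1], ], X[p[2], ]))
  expect_gt(mean(sims[same[upper.tri(same)]]),
            mean(sims[!same[upper.tri(same)]]) + 0.2)
  # rebuilding from a permuted gene order yields the same column multiset
  set.seed(20)
  perm <- sample(30L)
  Gp <- expression_matrix(sim$G$values[perm, ])
  T_p <- simulate_structured_annotations(Gp)
  sets <- function(T) sort(vapply(seq_len(ncol(T$values)), function(j)
    paste(sort(T$genes[T$values[, j] == 1L]), collapse = ","), ""))
  expect_identical(sets(T_e), sets(T_p))
})

test_that("random annotations conserve column margins exactly", {
  cfg <- simulation_config(I = 10L, K = 24L, n_blocks = 3L, seed = 23L)
  sim <- simulate_expression(cfg)
  T_e <- simulate_structured_annotations(sim$G)
  set.seed(1)
  T_r <- simulate_random_annotations(T_e, r = 2L)
  expect_identical(ncol(T_r$values), 2L * ncol(T_e$values))
  expect_identical(as.integer(T_r$col_margins),
                   rep(as.integer(T_e$col_margins), 2L))
  # every column is a permutation of its source column
  expect_true(all(T_r$values %in% c(0L, 1L)))
  # r = 2 on a 4 x 2 toy matrix -> 4 columns, each a source permutation
  toy <- coexgo:::.annotation_matrix(
    matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L), 4, 2,
           dimnames = list(paste0("g", 1:4), c("fa", "fb"))))
  set.seed(2)
  toy_r <- simulate_random_annotations(toy, r = 2L)
  expect_identical(ncol(toy_r$values), 4L)
  expect_identical(as.integer(toy_r$col_margins), c(2L, 3L, 2L, 3L))
})

test_that("permuted columns decouple annotations from the planted blocks", {
  cfg <- simulation_config(I = 10L, K = 120L, n_blocks = 8L, seed = 29L)
  sim <- simulate_expression(cfg)
  T_e <- simulate_structured_annotations(sim$G)
  set.seed(3)
  T_r <- simulate_random_annotations(T_e, r = 1L)
  cramer <- function(col, truth) {
    tab <- table(col, truth)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    sqrt(unname(chi$statistic) / (length(col)))
  }
  mid <- which(T_e$col_margins >= 10 & T_e$col_margins <= 60)
  v_struct <- mean(vapply(mid, function(j)
    cramer(T_e$values[, j], sim$block_truth), numeric(1)))
  v_rand <- mean(vapply(mid, function(j)
    cramer(T_r$values[, j], sim$block_truth), numeric(1)))
  expect_lt(v_rand, 0.5 * v_struct)
})

test_that("simulate_dataset assembles provenance, ratio and determinism", {
  cfg <- simulation_config(I = 10L, K = 30L, n_blocks = 3L, r = 3L,
                           seed = 37L)
  ds <- simulate_dataset(cfg)
  expect_identical(sum(ds$column_provenance == "random"),
                   3L * sum(ds$column_provenance == "structured"))
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$G$values, ds2$G$values)
  expect_identical(ds$T$values, ds2$T$values)
  # the scale of the benchmark configuration is representable
  cfg1 <- simulation_config(I = 10L, K = 300L, r = 1L, seed = 1L)
  expect_identical(cfg1$n_blocks, 20L)
})
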