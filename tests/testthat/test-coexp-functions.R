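test_that("correlation distance matches hand values and its range", {
  base <- c(1.2, -0.4, 0.8, 2.1, -1.5, 0.3)
  values <- rbind(g1 = base, g2 = 2 * base + 3, g3 = -base,
                  g4 = stats::rnorm(6))
  colnames(values) <- paste0("s", 1:6)
  G <- expression_matrix(values)
  d <- correlation_distance(G)
  # identical profile up to a positive affine map -> distance 0
  expect_equal(d["g1", "g2"], 0, tolerance = 1e-12)
  # sign-flipped profile -> distance 2
  expect_equal(d["g1", "g3"], 2, tolerance = 1e-12)
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))

  # hand Pearson value: (1,2,3) vs (1,3,2) correlate at 0.5
  G2 <- expression_matrix(rbind(a = c(1, 2, 3), b = c(1, 3, 2),
                                c = c(2, 1, 3)))
  expect_equal(correlation_distance(G2)["a", "b"], 0.5, tolerance = 1e-12)

  expect_error(correlation_distance(G, genes = "g1"), "at least 2")
})

test_that("tree cut by relative inertia loss finds planted block counts", {
  two <- make_block_expression(n_blocks = 2L, block_size = 5L, anti = TRUE,
                               seed = 11L)
  d2 <- correlation_distance(two$G)
  lab2 <- cut_tree_by_relative_inertia(coexgo:::.ward_tree(d2), d2, 8L)
  expect_identical(length(unique(lab2)), 2L)
  expect_identical(length(unique(lab2[1:5])), 1L)
  expect_identical(length(unique(lab2[6:10])), 1L)
  expect_false(lab2[1] == lab2[6])

  three <- make_block_expression(n_blocks = 3L, block_size = 6L,
                                 noise = 0.1, seed = 12L)
  d3 <- correlation_distance(three$G)
  lab3 <- cut_tree_by_relative_inertia(coexgo:::.ward_tree(d3), d3, 8L)
  expect_identical(length(unique(lab3)), 3L)
  # brute-force inertia sequence confirms the elbow at L = 3
  W <- vapply(1:9, function(L)
    coexgo:::.partition_inertia(d3, stats::cutree(coexgo:::.ward_tree(d3), L)),
    numeric(1))
  gains <- W[-length(W)] - W[-1]
  expect_identical(which.max(gains[1:7] / gains[2:8]) + 1L, 3L)

  # n = 2 forces the split
  Gp <- expression_matrix(rbind(a = c(1, 2, 3, 1), b = c(4, 0, 2, 2)))
  dp <- correlation_distance(Gp)
  expect_identical(unname(cut_tree_by_relative_inertia(
    coexgo:::.ward_tree(dp), dp, 5L)), c(1L, 2L))
})

test_that("function coexpression filtering separates planted from random", {
  fix <- make_block_expression(n_blocks = 4L, block_size = 10L, I = 10L,
                               seed = 13L)
  set.seed(1)
  planted <- test_function_coexpression(fix$G, which(fix$blocks == 2L),
                                        B = 500L)
  expect_true(planted$is_coexpressed)
  expect_lt(planted$p_value, 0.02)

  # random gene sets from uncorrelated data: p roughly uniform
  set.seed(2)
  Gnull <- expression_matrix(matrix(rnorm(80 * 10), 80, 10,
                                    dimnames = list(sprintf("g%02d", 1:80),
                                                    NULL)))
  ps <- replicate(60, test_function_coexpression(
    Gnull, sample(80, 8), B = 200L)$p_value)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.5), 0.3)

  expect_error(test_function_coexpression(fix$G, 3L), "singleton")
})

test_that("build_t_coexp keeps coexpressed functions whole and splits others", {
  fix <- make_block_expression(n_blocks = 2L, block_size = 6L, anti = TRUE,
                               seed = 21L)
  genes <- fix$G$genes
  # one function inside a block, one spanning the two anti-correlated blocks
  assoc <- rbind(data.frame(gene = genes[1:6], term = "inblock"),
                 data.frame(gene = genes[c(1:4, 7:10)], term = "spanning"))
  T <- build_annotation_matrix(assoc, genes)
  tc <- build_t_coexp(fix$G, T, B = 300L, seed = 7L)
  parts <- tc$partitions
  names(parts) <- vapply(parts, `[[`, "", "fun")
  expect_true(parts$inblock$coexpressed_whole)
  expect_identical(parts$spanning$L, 2L)
  # the split recovers the two planted blocks
  expect_setequal(parts$spanning$sub_clusters[[1]], genes[1:4])
  expect_setequal(parts$spanning$sub_clusters[[2]], genes[7:10])
  # margins of the split columns sum to the function margin
  expect_equal(sum(tc$col_margins[tc$col_function == "spanning"]),
               unname(T$col_margins["spanning"]))
})

test_that("the decomposition preserves the margin structure of T", {
  ds <- make_small_dataset(seed = 31L, K = 40L, n_blocks = 4L)
  tc <- build_t_coexp(ds$G, ds$T, B = 200L, seed = 3L)
  per_fun <- tapply(tc$col_margins,
                    factor(tc$col_function, levels = ds$T$functions), sum)
  expect_equal(as.integer(per_fun), as.integer(ds$T$col_margins))
  expect_equal(as.integer(tc$row_margins), as.integer(ds$T$row_margins))
  expect_identical(tc$total, ds$T$total)
  # deterministic under a fixed seed
  tc2 <- build_t_coexp(ds$G, ds$T, B = 200L, seed = 3L)
  expect_identical(tc$values, tc2$values)
})

test_that("alpha0 >= 1 conserves every function whole so T_coexp equals T", {
  ds <- make_small_dataset(seed = 33L, K = 30L, n_blocks = 3L)
  tc <- build_t_coexp(ds$G, ds$T, alpha0 = 1)
  expect_identical(unname(tc$values), unname(ds$T$values))
  expect_true(all(vapply(tc$partitions, `[[`, TRUE, "coexpressed_whole")))
})

test_that("build_t_coexp validates its inputs", {
  ds <- make_small_dataset(seed = 35L, K = 20L, n_blocks = 2L)
  # singleton function rejected with advice
  X <- ds$T$values
  X[, 1] <- 0L; X[1, 1] <- 1L
  expect_error(build_t_coexp(ds$G, coexgo:::.annotation_matrix(X)),
               "filter_functions")
  # mismatched universes rejected
  Gsub <- expression_matrix(ds$G$values[-1, ])
  expect_error(build_t_coexp(Gsub, ds$T), "universes differ")
})
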