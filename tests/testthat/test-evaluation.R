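test_that("coexpression indicator reaches its analytic extremes", {
  base <- stats::rnorm(8)
  # positive affine maps of one profile: every correlation is 1
  Gmax <- expression_matrix(rbind(a = base, b = 2 * base + 3,
                                  c = 0.5 * base - 1))
  expect_equal(coexpression_indicator(Gmax, c("a", "b", "c")), 1,
               tolerance = 1e-12)
  # even size 4: two perfect pairs, anti-correlated across -> -1/(n-1)
  Geven <- expression_matrix(rbind(a = base, b = base, c = -base,
                                   d = -base))
  expect_equal(coexpression_indicator(Geven, c("a", "b", "c", "d")), -1 / 3,
               tolerance = 1e-12)
  # odd size 3: two-block worst case -> -1/n
  expect_equal(coexpression_indicator(Geven, c("a", "b", "c")), -1 / 3,
               tolerance = 1e-12)
  expect_error(coexpression_indicator(Gmax, "a"), "at least 2")
})

test_that("homogeneity indicator reaches its analytic extremes and matches the oracle", {
  # identical profiles -> 1
  X1 <- rbind(g1 = c(1L, 1L, 0L), g2 = c(1L, 1L, 0L), g3 = c(1L, 1L, 0L),
              g4 = c(0L, 0L, 1L))
  colnames(X1) <- paste0("f", 1:3)
  T1 <- coexgo:::.annotation_matrix(X1)
  expect_equal(biological_homogeneity_indicator(T1, c("g1", "g2", "g3")), 1,
               tolerance = 1e-12)
  # fully disjoint, private-per-gene profiles -> 0
  X0 <- diag(1L, 4)
  dimnames(X0) <- list(paste0("g", 1:4), paste0("f", 1:4))
  T0 <- coexgo:::.annotation_matrix(X0)
  expect_equal(biological_homogeneity_indicator(T0, paste0("g", 1:3)), 0,
               tolerance = 1e-12)
  # 3-gene cluster in a 6-gene, 4-function toy matrix: term-by-term oracle
  set.seed(6)
  T6 <- make_random_annotation(K = 6L, J = 4L, seed = 6L)
  idx <- c(1L, 3L, 5L)
  expect_equal(biological_homogeneity_indicator(T6, idx),
               bhi_oracle(T6$values, idx), tolerance = 1e-12)
  # always within [0, 1] on random clusters
  T12 <- make_random_annotation(K = 12L, J = 8L, seed = 61L)
  for (i in 1:50) {
    v <- biological_homogeneity_indicator(T12, sample(12L, sample(2:8, 1)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("whole-universe homogeneity matches the contingency statistic", {
  T <- make_random_annotation(K = 10L, J = 6L, seed = 55L)
  obs <- biological_homogeneity_indicator(T, seq_len(10L))
  chi2 <- suppressWarnings(stats::chisq.test(T$values, correct = FALSE))
  expect_equal(obs, 1 - unname(chi2$statistic) / (T$total * (10 - 1)),
               tolerance = 1e-10)
})

test_that("permutation p-values behave as proportions of strict exceedance", {
  set.seed(10)
  x <- stats::rnorm(100)
  ind <- function(idx) mean(x[idx])
  # observed above every null value -> p = 0
  top <- order(x, decreasing = TRUE)[1:5]
  set.seed(11)
  expect_identical(permutation_pvalue(ind, 100L, top, B = 300L), 0)
  # symmetric null, observed at its exact centre -> p near 0.5
  xs <- c(stats::rnorm(50))
  x <- c(xs, -xs)   # exactly symmetric scores
  pair <- c(1L, 51L)  # sums to zero, the null median
  set.seed(12)
  p <- permutation_pvalue(ind, 100L, pair, B = 1000L)
  expect_gt(p, 0.42); expect_lt(p, 0.58)
  # singleton clusters are refused with an absent value
  expect_true(is.na(permutation_pvalue(ind, 100L, 3L, B = 10L)))
  # relabeling genes leaves the p-value invariant up to Monte-Carlo noise
  set.seed(13); p1 <- permutation_pvalue(ind, 100L, c(2L, 7L, 9L), B = 800L)
  set.seed(14); perm <- sample(100L)
  xp <- x[perm]
  indp <- function(idx) mean(xp[idx])
  set.seed(13)
  p2 <- permutation_pvalue(indp, 100L, match(c(2L, 7L, 9L), perm), B = 800L)
  expect_lt(abs(p1 - p2), 0.08)
})

test_that("evaluate_partition scores planted, null and singleton partitions", {
  ds <- make_small_dataset(seed = 71L, K = 60L, n_blocks = 4L)
  truth <- gene_partition(stats::setNames(ds$block_truth, ds$G$genes))
  ev <- evaluate_partition(ds$G, ds$T, truth, B = 300L, alpha = 0.05,
                           seed = 5L)
  expect_equal(ev$summary$pct_both, 100)
  expect_true(all(ev$clusters$ci > 0.5))
  expect_true(all(ev$clusters$bhi_pvalue < 0.05))

  # all-singleton partition: nothing is tested, nothing significant
  singl <- gene_partition(stats::setNames(seq_len(60L), ds$G$genes))
  evs <- evaluate_partition(ds$G, ds$T, singl, B = 50L, seed = 5L)
  expect_equal(evs$summary$pct_both, 0)
  expect_equal(evs$summary$n_singletons, 60L)
  expect_true(all(is.na(evs$clusters$ci_pvalue)))

  # unstructured data: proportions near or below the threshold
  set.seed(9)
  Gn <- expression_matrix(matrix(rnorm(80 * 10), 80, 10,
                                 dimnames = list(sprintf("g%02d", 1:80),
                                                 NULL)))
  Tn <- make_random_annotation(K = 80L, J = 40L, p = 0.15, seed = 91L)
  rnd <- gene_partition(stats::setNames(sample(rep(1:8, each = 10)),
                                        Gn$genes))
  evn <- evaluate_partition(Gn, Tn, rnd, B = 400L, alpha = 0.05, seed = 6L)
  expect_lte(evn$summary$pct_both, 25)
})
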