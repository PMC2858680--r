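test_that("fisher_exact reproduces hand-enumerated p-values", {
  # support x in 0..4 for margins (4,4)x(4,4): two-sided p = 34/70
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  # two extreme tables of probability 1/252 each
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
  # an all-zero row forces a unique table
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "integer|negative")
})

test_that("fisher_exact is invariant to row and column permutations", {
  set.seed(111)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 5), 2, 3)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[, c(3, 1, 2)]), p, tolerance = 1e-12)
  }
  tab2 <- matrix(c(8, 2, 3, 9), 2)
  expect_equal(fisher_exact(tab2[, 2:1]), fisher_exact(tab2),
               tolerance = 1e-12)
})

test_that("fisher_exact agrees with enumeration oracles and fisher.test", {
  set.seed(112)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  for (i in 1:30) {
    tab <- matrix(rpois(6, sample(1:6, 1)), 2, 3)
    if (any(colSums(tab) == 0) || sum(tab) == 0) next
    expect_equal(fisher_exact(tab), oracle_fisher_2x3(tab),
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("compare_arm_timing builds the binned table and respects the scheme", {
  d <- default_design()
  cnt <- counts_from_props(c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1), n_scored = 50)
  same <- compare_arm_timing(cnt, cnt, d)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  early <- counts_from_props(c(0.4, 0.4, 0, 0, 0, 0), n_scored = 25)
  late <- counts_from_props(c(0, 0, 0, 0, 0.4, 0.4), n_scored = 25)
  res3 <- compare_arm_timing(early, late, d, scheme = "bins3")
  tab3 <- rbind(c(20, 0, 0), c(0, 0, 20))
  expect_equal(res3$p, oracle_fisher_2x3(tab3), tolerance = 1e-12)

  res2 <- compare_arm_timing(early, late, d, scheme = "late_vs_rest")
  expect_equal(res2$p,
               fisher_exact(matrix(c(20, 0, 0, 20), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(res2$test, "fisher_2x2")

  empty <- counts_from_props(rep(0, 6), n_scored = 0)
  expect_error(compare_arm_timing(empty, cnt, d), "empty counts")
})

test_that("spearman matches the d^2 formula, handles reversal and monotone transforms", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_test(x, x)$rho, 1)
  expect_equal(spearman_test(x, rev(x))$rho, -1)
  # rho = 1 - 6 * sum(d^2) / (n^3 - n) = 1 - 24/120
  s <- spearman_test(x, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)

  # invariance under strictly monotone transforms
  y <- c(3, 1, 4, 1.5, 9, 2.6)
  base_res <- spearman_test(seq_along(y), y)
  expect_equal(spearman_test(exp(seq_along(y)), y^3 + 1)$rho,
               base_res$rho)

  expect_error(spearman_test(x, rep(2, 5)), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("spearman p-values match cor.test (exact small-n and t approximation)", {
  set.seed(113)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    s <- spearman_test(x, y)
    ct <- cor.test(x, y, method = "spearman")
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    # both exact, but two-sided conventions differ slightly; they agree
    # within a factor comfortably below 2 and on significance calls
    expect_lt(abs(s$p - ct$p.value), 0.05)
  }
  x <- rnorm(30); y <- x + rnorm(30)
  s <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(s$p, ct$p.value, tolerance = 1e-6)
})

test_that("bonferroni thresholds divide the family level by the comparison count", {
  expect_identical(bonferroni_threshold(0.05, 20), 0.0025)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  expect_error(bonferroni_threshold(0.05, 0), "k")
  res <- new_comparison <- spearman_test(1:5, c(2, 1, 4, 3, 5),
                                         alpha_family = 0.05, k = 20)
  expect_equal(res$threshold, 0.0025)
  expect_identical(res$significant, res$p < 0.0025)
})
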