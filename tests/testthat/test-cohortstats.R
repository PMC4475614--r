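test_that("Kruskal-Wallis H matches the hand formula and handles degenerate input", {
  # ranks 1..6, rank sums 6 and 15: H = 12/42 * (12 + 75) - 21 = 3.857
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(res$df, 1)
  expect_identical(res$direction, "b")
  # identical groups: H = 0, p = 1
  res0 <- kruskal_wallis(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two non-empty groups")
})

test_that("small-n exact permutation p equals exhaustive enumeration", {
  set.seed(2)
  for (rep_i in 1:5) {
    vals <- sample(20, 6)
    g <- rep(c("a", "b"), each = 3)
    res <- kruskal_wallis(vals, g)
    # independent oracle: enumerate all C(6,3) group assignments, score
    # each with stats::kruskal.test
    h_obs <- kruskal.test(vals, factor(g))$statistic
    picks <- combn(6, 3)
    h_all <- apply(picks, 2, function(ix) {
      gg <- rep("b", 6); gg[ix] <- "a"
      kruskal.test(vals, factor(gg))$statistic
    })
    expect_equal(res$p_exact, mean(h_all >= h_obs - 1e-12))
  }
  # unbalanced three-group case
  vals <- c(3, 9, 1, 7, 2, 8, 5)
  g <- c("a", "a", "b", "b", "b", "c", "c")
  res <- kruskal_wallis(vals, g)
  h_obs <- kruskal.test(vals, factor(g))$statistic
  labs <- unique(g)
  perms <- combn(7, 2, simplify = FALSE)
  h_all <- unlist(lapply(perms, function(ia) {
    rest <- setdiff(1:7, ia)
    lapply(combn(rest, 3, simplify = FALSE), function(ib) {
      gg <- rep("c", 7); gg[ia] <- "a"; gg[ib] <- "b"
      kruskal.test(vals, factor(gg))$statistic
    })
  }))
  expect_equal(res$p_exact, mean(h_all >= h_obs - 1e-12))
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(3)
  vals <- rnorm(30); g <- sample(c("x", "y", "z"), 30, replace = TRUE)
  a <- kruskal_wallis(vals, g)
  b <- kruskal_wallis(exp(vals), g)
  c3 <- kruskal_wallis(vals^3, g)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$statistic, c3$statistic)
})

test_that("unknown annotations are dropped listwise", {
  vals <- c(1, 2, 3, 4, 100, 200)
  g <- c("a", "a", "b", "b", "unknown", NA)
  res <- kruskal_wallis(vals, g)
  expect_equal(sum(res$groups), 4)
})

test_that("the t-transform significance matches both the printed formula and cor.test", {
  s <- correlation_significance(0.289, 88)
  expect_equal(s$t, 0.289 / sqrt((1 - 0.289^2) / 86))
  expect_equal(s$p_value, 6.2e-3, tolerance = 0.1)
  s2 <- correlation_significance(0.225, 649)
  expect_equal(s2$p_value, 6.5e-9, tolerance = 0.1)
  # cross-check against cor.test on data with that exact correlation
  set.seed(4)
  x <- rnorm(40); y <- rnorm(40)
  r <- cor(x, y)
  ct <- cor.test(x, y)
  s3 <- correlation_significance(r, 40)
  expect_equal(s3$t, unname(ct$statistic))
  expect_equal(s3$p_value, ct$p.value)
  # limits and errors
  expect_equal(correlation_significance(0, 30)$p_value, 1)
  lim <- correlation_significance(1, 10)
  expect_true(lim$limit); expect_equal(lim$p_value, 0)
  expect_error(correlation_significance(0.5, 2), "at least 3")
})

test_that("correlation p decreases in |r| at fixed n and in n at fixed |r|", {
  p_by_r <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(r) correlation_significance(r, 50)$p_value, 0)
  expect_true(all(diff(p_by_r) < 0))
  p_by_n <- vapply(c(5, 10, 50, 200, 1000),
                   function(n) correlation_significance(0.3, n)$p_value, 0)
  expect_true(all(diff(p_by_n) < 0))
})

test_that("pearson_log2 handles trivial and error cases", {
  x <- c(1.5, 2.3, 3.1, 4.8, 5.2)
  expect_equal(pearson_log2(x, x)$r, 1)
  expect_equal(pearson_log2(x, -x)$r, -1)
  expect_error(pearson_log2(x, rep(2, 5)), "zero variance")
  expect_error(pearson_log2(x, x[1:4]), "equal length")
})

test_that("generated cohorts carry their planted correlation", {
  co <- gen_cohort(n_per_group = c(`not amplified` = 500, amplified = 149),
                   target_r = 0.3, seed = 6)
  res <- pearson_log2(co$expression[, "SPR"], co$expression[, "ODC1"])
  expect_equal(res$n, 649)
  expect_lt(abs(res$r - 0.3), 2 / sqrt(649) + 0.02)
})

test_that("ranked dual-gene export orders by the ranking gene with stable ties", {
  expr <- matrix(c(2, 1, 1, 5, 6, 7), ncol = 2,
                 dimnames = list(c("s3", "s1", "s2"), c("G1", "G2")))
  co <- cohort_matrix(expr, data.frame(sample = c("s3", "s1", "s2"),
                                       mycn = c("amplified", "not amplified", "unknown")))
  tab <- ranked_dual_gene_export(co, "G1", "G2")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$sample, c("s1", "s2", "s3"))  # ties s1/s2 by id
  expect_true(all(diff(tab$G1) >= 0))
  expect_true("mycn" %in% names(tab))
  # re-ranking by the other gene permutes, never drops, rows
  tab2 <- ranked_dual_gene_export(co, "G2", "G1")
  expect_setequal(tab$sample, tab2$sample)
  expect_error(ranked_dual_gene_export(co, "NOPE", "G1"), "not in cohort")
})

test_that("the one-tailed paired t-test matches a hand-computed oracle", {
  treated <- c(62, 71, 58)
  control <- c(98, 95, 101)
  d <- control - treated
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  res <- paired_onetailed_t(treated, control)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, pt(t_hand, df = 2, lower.tail = FALSE))
  # no change: t = 0, one-tailed p = 0.5
  expect_equal(paired_onetailed_t(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
  # constant non-zero differences have no estimable variance
  expect_error(paired_onetailed_t(c(1, 2, 3), c(2, 3, 4)), "constant")
})
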