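test_that("global_proportion_test matches the exact binomial tail", {
  # 80 of 100 informative bins higher in a
  a <- make_profile(c(rep(60, 80), rep(40, 20)), id = "A")
  b <- make_profile(rep(50, 100), id = "B")
  got <- global_proportion_test(a, b)
  expect_equal(got$statistic, 0.8)
  # independent tail sum: sum_{k>=80 or k<=20} C(100,k)/2^100
  tail_p <- sum(choose(100, c(0:20, 80:100)) / 2^100)
  expect_equal(got$p_value, tail_p, tolerance = 1e-12)
  expect_lt(got$p_value, 1e-8)

  even <- global_proportion_test(
    make_profile(c(rep(60, 50), rep(40, 50)), id = "A"),
    make_profile(rep(50, 100), id = "B"))
  expect_gt(even$p_value, 0.9)

  tied <- make_profile(rep(50, 40), id = "T")
  expect_error(global_proportion_test(tied, tied), "informative")
})

test_that("global_proportion_test is symmetric under profile swap", {
  set.seed(11)
  a <- make_profile(runif(60, 0, 100), id = "A")
  b <- make_profile(runif(60, 0, 100), id = "B")
  ab <- global_proportion_test(a, b)
  ba <- global_proportion_test(b, a)
  expect_equal(ab$statistic, 1 - ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  # pooled-call variant also runs and is symmetric in p
  expect_equal(global_proportion_test(a, b, "pooled")$p_value,
               global_proportion_test(b, a, "pooled")$p_value)
})

test_that("fisher_enrichment matches enumeration and stats::fisher.test", {
  universe <- paste0("g", 1:100)
  dmr <- universe[1:20]
  sets <- list(complete = universe[1:10],      # all 10 in the DMR list
               atnull = c(universe[1:2], universe[90:97]))  # overlap 2 = E[k]
  res <- fisher_enrichment(dmr, sets, universe)
  r1 <- res[res$term == "complete", ]
  expect_equal(r1$k, 10L)
  expect_equal(r1$p, oracle_fisher_p(10, 10, 20, 100), tolerance = 1e-12)
  expect_equal(r1$p,
               fisher.test(matrix(c(10, 0, 10, 80), 2))$p.value,
               tolerance = 1e-9)
  r2 <- res[res$term == "atnull", ]
  expect_equal(r2$p, 1.0)                      # observed table is the mode

  # Bonferroni multiplies by the number of terms tested, capped at 1
  five <- fisher_enrichment(dmr, rep(sets, length.out = 5), universe)
  expect_equal(five$p_bonf, pmin(1, five$p * 5))
  expect_true(all(five$p_bonf >= five$p))
  expect_true(all(five$p > 0 & five$p <= 1))
  expect_true(all(five$k <= pmin(five$K, five$n)))

  expect_error(fisher_enrichment(dmr, sets, character()), "empty")
})

test_that("two_sample_ttest follows the pooled-variance closed form", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  x <- c(1, 2, 3); y <- c(101, 102, 103)
  got <- two_sample_ttest(x, y)
  sp2 <- (sum((x - 2)^2) + sum((y - 102)^2)) / 4
  t_exp <- (2 - 102) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_exp)
  expect_equal(got$df, 4)
  expect_lt(got$p_value, 1e-4)

  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
  expect_error(two_sample_ttest(c(5, 5), c(5, 5)), "variance")
})

test_that("age_adjusted_regression recovers planted coefficients", {
  set.seed(3)
  meth <- c(10, 12, 40, 41, 40, 39)
  age <- c(0, 1, 22, 100, 200, 300)
  expr <- 0.02 * meth + rnorm(6, 0, 1e-6)
  fit <- age_adjusted_regression(
    data.frame(age = age, methylation = meth, expression = expr))
  expect_equal(fit$coefficient, 0.02, tolerance = 1e-4)
  expect_lt(fit$p_value, 1e-6)
  expect_equal(fit$direction, "positive")

  # expression driven only by age: compare against the normal-equation oracle
  set.seed(4)
  expr2 <- 0.5 + 0.01 * age + rnorm(6, 0, 0.01)
  series2 <- data.frame(age = age, methylation = meth, expression = expr2)
  fit2 <- age_adjusted_regression(series2)
  X <- cbind(1, meth, age)
  beta <- solve(t(X) %*% X, t(X) %*% expr2)
  expect_equal(fit2$coefficient, beta[2], tolerance = 1e-10)
  expect_lt(abs(fit2$coefficient), 3 * fit2$se)

  expect_error(age_adjusted_regression(
    data.frame(age = 1:3, methylation = 1:3, expression = 1:3)),
    "at least 4")
  expect_error(age_adjusted_regression(
    data.frame(age = age, methylation = age, expression = expr2)),
    "degenerate")
})

test_that("bh_fdr reproduces the hand-computed step-up and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  p <- runif(40)
  adj <- bh_fdr(p)
  # input order preserved: adjusted values sorted like sorted p
  expect_equal(adj[order(p)], sort(adj))
  # monotone in the sorted domain, never below the raw p
  expect_true(all(diff(sort(adj)) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  # matches the step-up definition computed directly
  ord <- order(p)
  manual <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))
  expect_equal(adj[ord], pmin(1, manual))
})

test_that("hierarchical_cluster is deterministic with documented tie-breaks", {
  m <- cbind(s1 = c(0, 0, 0), s2 = c(10, 10, 10), s3 = c(0, 0, 0))
  cl <- hierarchical_cluster(m, axis = "samples")
  # the identical pair (s1, s3) merges first, at height 0
  expect_equal(cl$tree$height[1], 0)
  expect_equal(sort(-cl$tree$merge[1, ]), c(1, 3))

  two <- hierarchical_cluster(cbind(a = c(0, 0), b = c(5, 5)), axis = "samples")
  expect_equal(two$order, c("a", "b"))

  # two well-separated blocks recovered at the 2-cluster cut
  blocks <- cbind(a1 = c(0, 1), a2 = c(1, 0), b1 = c(50, 51), b2 = c(51, 50))
  cut <- cut_clusters(hierarchical_cluster(blocks, axis = "samples"), 2)
  expect_equal(cut[["a1"]], cut[["a2"]])
  expect_equal(cut[["b1"]], cut[["b2"]])
  expect_false(cut[["a1"]] == cut[["b1"]])

  # constant matrix: all-zero distances, clustering proceeds
  const <- hierarchical_cluster(matrix(5, 3, 4), axis = "samples")
  expect_equal(length(const$order), 4L)
})

test_that("clustering partitions are invariant to column permutation", {
  set.seed(21)
  m <- matrix(runif(60, 0, 100), nrow = 6)
  colnames(m) <- paste0("s", 1:10)
  base <- hierarchical_cluster(m, axis = "samples")
  perm <- sample(10)
  shuf <- hierarchical_cluster(m[, perm], axis = "samples")
  for (k in 2:5) {
    a <- cut_clusters(base, k)
    b <- cut_clusters(shuf, k)[names(a)]
    # same partition up to label renumbering
    expect_equal(length(unique(paste(a, b))), length(unique(a)))
  }
})

test_that("GMT and panel readers round-trip", {
  gmt <- c("term1\tdesc\tg1\tg2\tg3", "term2\tdesc\tg2\tg4")
  sets <- read_gmt(gmt)
  expect_equal(sets$term1, c("g1", "g2", "g3"))
  expect_error(read_gmt("term_only\tdesc"), "malformed")

  vals <- matrix(c(10.5, 20, 30, 40), 2,
                 dimnames = list(c("siteA", "siteB"), c("x1", "x2")))
  p <- sample_panel(vals, age = c("P0", "P21"), condition = c("CNV", "CNV"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, path)
  q <- read_panel(path)
  expect_equal(q$values, p$values)
  expect_equal(q$age, p$age)
  expect_equal(q$condition, p$condition)

  expect_error(sample_panel(matrix(c(1, NA), 1, 2), c("P0", "P0"),
                            c("CNV", "CNV")), "missing")
  expect_error(sample_panel(matrix(150, 1), "P0", "CNV"), "percent")
})
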