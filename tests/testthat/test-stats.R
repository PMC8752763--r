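test_that("Mann-Whitney uses exact enumeration on small tie-free samples", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(t1$p_value, 1 / 20)                 # 1 of C(6,3) orderings
  t2 <- mann_whitney(c(1, 2, 3), c(1.5, 2.5, 3.5), alternative = "two_sided")
  expect_true(grepl("exact", t2$method))
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # symmetric case: identical distributions
  t3 <- mann_whitney(c(1, 3, 5), c(2, 4, 6), alternative = "two_sided")
  expect_gt(t3$p_value, 0.5)
})

test_that("U statistic and ROC AUC are the same quantity", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(12)  # scores of positives
    y <- rnorm(9)   # scores of negatives
    u <- mann_whitney(x, y)$statistic
    auc <- roc_auc(c(x, y), rep(c(1, 0), c(12, 9)))
    expect_equal(u / (12 * 9), auc, tolerance = 1e-12)
  }
})

test_that("permutation Spearman handles monotone, reversed and constant input", {
  x <- 1:10
  expect_equal(spearman_perm(x, x^2, n_perm = 99, seed = 1)$statistic, 1)
  expect_equal(spearman_perm(x, rev(x), n_perm = 99, seed = 1)$statistic, -1)
  expect_error(spearman_perm(x, rep(1, 10)), "constant")
  t <- spearman_perm(x, x, n_perm = 99, seed = 1)
  expect_gte(t$p_value, 1 / 100)                   # add-one convention floor
})

test_that("permutation Spearman p matches exhaustive enumeration at n = 8", {
  set.seed(21)
  x <- rnorm(8)
  y <- 0.6 * x + rnorm(8, sd = 0.8)
  rho_obs <- cor(rank(x), rank(y))
  perms <- all_perms(8L)
  rx <- rank(x)
  ry <- rank(y)
  rho_all <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  p_exact <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  t <- spearman_perm(x, y, n_perm = 4000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(t$p_value - p_exact), 4 * se + 1 / 4000)
})

test_that("slope-equality permutation test is calibrated and deterministic", {
  set.seed(3)
  x <- runif(40, 6, 30)
  y <- 3 * x + rnorm(40, sd = 10)
  t_null <- slope_equality_perm(x[1:20], y[1:20], x[21:40], y[21:40],
                                n_perm = 400, seed = 2)
  expect_gt(t_null$p_value, 0.1)                   # exchangeable groups
  expect_lt(t_null$p_value, 0.9)
  t_rep <- slope_equality_perm(x[1:20], y[1:20], x[21:40], y[21:40],
                               n_perm = 400, seed = 2)
  expect_identical(t_rep$p_value, t_null$p_value)
  expect_error(slope_equality_perm(1:2, 1:2, 1:5, 1:5), ">= 3 points")
})

test_that("set-overlap chi-square detects identity and conserves margins", {
  universe <- sprintf("f%03d", 1:100)
  res <- set_overlap_chi2(universe[1:50], universe[1:50], universe)
  expect_lt(res$test$p_value, 1e-10)
  expect_equal(sum(res$table), 100)
  disj <- set_overlap_chi2(universe[1:40], universe[41:100], universe)
  expect_equal(rowSums(disj$table), c(in_query = 40, out_query = 60),
               ignore_attr = TRUE)
  expect_error(set_overlap_chi2("a", "b", character(0)), "empty universe")
  expect_error(set_overlap_chi2("not_there", universe[1], universe), "subsets")
})

test_that("independent random sets give a null-sized chi-square", {
  set.seed(9)
  stats <- replicate(200, {
    u <- sprintf("f%03d", 1:80)
    q <- sample(u, 30)
    r <- sample(u, 30)
    set_overlap_chi2(q, r, u)$test$statistic
  })
  expect_lt(abs(mean(stats) - 1), 0.35)            # 1-df chi-square mean is 1
})

test_that("per-child subsampled correlation collapses correctly", {
  rec <- make_records(sprintf("s%d", 1:6), sprintf("S%d", 1:6),
                      c(8, 10, 12, 14, 16, 18), "homecare")
  v <- stats::setNames(rec$age_months, rec$sample_id)
  out <- per_child_subsample_correlation(v, rec, n_iter = 10, seed = 1)
  expect_true(all(out$iterations$rho == 1))        # values = age exactly
  # single samples per child: no sampling variability
  expect_equal(out$summary[["sd"]], 0)
  expect_error(per_child_subsample_correlation(v[1:2], rec[1:2, ], 5, 1),
               "3 children")
})
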