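# Paired rank-mean permutation test and discrete FDR.

test_that("a perfectly separating feature attains the permutation floor", {
  # 8 groups of (1 homecare, 2 daycare); one feature present only in daycare
  n_grp <- 8L
  ids <- character(0); labels <- integer(0); groups <- character(0)
  for (g in seq_len(n_grp)) {
    ids <- c(ids, sprintf("g%d_h", g), sprintf("g%d_d1", g), sprintf("g%d_d2", g))
    labels <- c(labels, 0L, 1L, 1L)
    groups <- c(groups, rep(sprintf("g%d", g), 3))
  }
  set.seed(1)
  tab <- matrix(rpois(length(ids) * 5, 20), length(ids), 5,
                dimnames = list(ids, paste0("f", 1:5)))
  # present only under label 1; kept small so the compositional shift on the
  # other features stays negligible
  tab[, 1] <- ifelse(labels == 1L, 5L, 0L)
  res <- rank_mean_paired_test(tab, labels, groups, n_perm = 2000, seed = 4)
  expect_gt(res$statistic[1], max(abs(res$statistic[-1])))
  expect_lt(res$p_value[1], 3 / 2000)              # near the add-one floor
  expect_gte(min(res$p_value), 1 / 2001)
})

test_that("two groups of two samples reproduce the exhaustive 4-assignment null", {
  tab <- matrix(c(10, 3, 8, 1,
                  2, 9, 1, 7), 4, 2,
                dimnames = list(paste0("s", 1:4), c("fa", "fb")))
  labels <- c(1L, 0L, 1L, 0L)
  groups <- c("g1", "g1", "g2", "g2")
  # exhaustive: each group has 2 label assignments -> 4 equally likely nulls
  frac <- tab / rowSums(tab)
  stat_for <- function(l) {
    vapply(seq_len(ncol(frac)), function(j) {
      r <- rank(frac[, j])
      mean(r[l == 1L]) - mean(r[l == 0L])
    }, numeric(1))
  }
  assigns <- list(c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L),
                  c(1L, 0L, 0L, 1L), c(0L, 1L, 0L, 1L))
  null_stats <- vapply(assigns, stat_for, numeric(2))
  obs <- stat_for(labels)
  p_exact <- vapply(1:2, function(j)
    mean(abs(null_stats[j, ]) >= abs(obs[j]) - 1e-12), numeric(1))
  res <- rank_mean_paired_test(tab, labels, groups, n_perm = 4000, seed = 11)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  # add-one estimates converge to the exhaustive p (values are multiples of 1/4)
  expect_equal(res$p_value, p_exact, tolerance = 0.05)
})

test_that("null data give uniform p-values and a single group is the unpaired test", {
  set.seed(8)
  n <- 40L
  tab <- matrix(rpois(n * 200, 10), n, 200,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:200)))
  labels <- rep(c(0L, 1L), each = n / 2)[sample(n)]
  res <- rank_mean_paired_test(tab, labels, groups = rep("all", n),
                               n_perm = 500, seed = 2)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  # single all-samples group = unpaired rank-mean statistic
  frac <- tab / rowSums(tab)
  manual <- vapply(seq_len(ncol(frac)), function(j) {
    r <- rank(frac[, j])
    mean(r[labels == 1L]) - mean(r[labels == 0L])
  }, numeric(1))
  expect_equal(res$statistic, manual, tolerance = 1e-12)
})

test_that("group hygiene: singleton groups excluded, single-label groups kept", {
  tab <- matrix(rpois(5 * 3, 10), 5, 3,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:3)))
  labels <- c(1L, 0L, 1L, 0L, 1L)
  groups <- c("a", "a", "b", "b", "lonely")
  expect_warning(res <- rank_mean_paired_test(tab, labels, groups,
                                              n_perm = 50, seed = 1),
                 "single-sample")
  expect_equal(res$n_samples, 4L)
})

test_that("dsFDR rejects the obvious, spares the null, and is monotone in alpha", {
  expect_error(dsfdr(1:3, matrix(numeric(0), 0, 3)), ">= 1 row")

  obs <- rep(0, 10)
  null <- matrix(rnorm(500), 50, 10)
  out <- dsfdr(obs, null, alpha = 0.1)
  expect_false(any(out$rejected))                  # all-zero statistics

  obs2 <- c(100, rnorm(9))
  null2 <- matrix(rnorm(500), 50, 10)              # nothing near 100
  out2 <- dsfdr(obs2, null2, alpha = 0.1)
  expect_true(out2$rejected[1])
  expect_equal(out2$q_value[1], 0)

  set.seed(33)
  obs3 <- c(rnorm(40), rnorm(10, mean = 4))
  null3 <- matrix(rnorm(50 * 200), 200, 50)
  r_strict <- dsfdr(obs3, null3, alpha = 0.05)$rejected
  r_loose <- dsfdr(obs3, null3, alpha = 0.2)$rejected
  expect_true(all(r_loose[r_strict]))              # superset at larger alpha
  # rejection set is downward-closed in |statistic|
  out3 <- dsfdr(obs3, null3, alpha = 0.1)
  if (any(out3$rejected)) {
    expect_gte(min(abs(obs3)[out3$rejected]), max(abs(obs3)[!out3$rejected]))
  }
})

test_that("matched differential abundance wrapper labels directions", {
  b <- generate_cohort(small_params(seed = 5))
  ag <- suppressMessages(greedy_anchor_match(b$records))
  da <- suppressMessages(diff_abundance(b$table, b$records, ag,
                                        n_perm = 300, seed = 9))
  expect_true(all(c("feature_id", "rank_mean_delta", "p_value", "q_value",
                    "rejected", "direction") %in% names(da)))
  expect_true(all(da$direction[da$rank_mean_delta > 0] == "daycare"))
  expect_true(all(da$p_value >= 1 / 301))
})
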