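test_that("feature-table reader round-trips and validates", {
  tab <- random_table(3, 4, seed = 1)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rownames(tab), tab,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_feature_table(path)
  expect_identical(unname(got), unname(tab))
  expect_identical(dimnames(got), dimnames(tab))

  # samples-as-columns orientation transposes
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(feature_id = colnames(tab), t(tab),
                                check.names = FALSE),
                     path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_feature_table(path2, "samples_cols"), got)

  # negative count rejected with coordinates
  bad <- tab
  bad[2, 3] <- -2L
  path3 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rownames(bad), bad,
                                check.names = FALSE),
                     path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_feature_table(path3), "s2.*f3")

  # header-only file
  path4 <- tempfile(fileext = ".tsv")
  writeLines("sample_id\tf1\tf2", path4)
  expect_error(read_feature_table(path4), "no samples")
})

test_that("metadata reader enforces the design invariants", {
  base <- data.frame(sample_id = c("a", "b"), subject_id = c("S1", "S2"),
                     age_months = c(10, 11),
                     care_setting = c("daycare", "homecare"),
                     facility = c("A", ""), class_id = c("A1", ""),
                     timepoint = c("1", ""), stringsAsFactors = FALSE)
  write_md <- function(df) {
    p <- tempfile(fileext = ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  rec <- read_metadata(write_md(base))
  expect_true(is.na(rec$facility[2]))   # homecare with empty facility is valid
  expect_identical(rec$timepoint[1], 1L)

  dup <- base
  dup$sample_id <- c("a", "a")
  expect_error(read_metadata(write_md(dup)), "duplicate sample_id")

  tp6 <- base
  tp6$timepoint[1] <- "6"
  expect_error(read_metadata(write_md(tp6)), "out of range")

  nofac <- base
  nofac$facility[1] <- ""
  expect_error(read_metadata(write_md(nofac)), "facility")

  hc_tp <- base
  hc_tp$timepoint[2] <- "2"
  expect_error(read_metadata(write_md(hc_tp)), "must not carry")
})

test_that("rarefaction conserves depth, drops shallow samples, reproduces by seed", {
  tab <- rbind(s1 = c(4000L, 0L), s2 = c(2000L, 1999L), s3 = c(3000L, 1500L))
  colnames(tab) <- c("f1", "f2")
  expect_message(rar <- rarefy(tab, 4000, seed = 1), "dropping 1 sample")
  expect_identical(rownames(rar), c("s1", "s3"))
  expect_identical(unname(rar["s1", ]), c(4000L, 0L))  # forced, no choice
  expect_true(all(rowSums(rar) == 4000L))

  big <- random_table(12, 30, seed = 3, lambda = 40)
  r1 <- rarefy(big, 200, seed = 9)
  r2 <- rarefy(big, 200, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(rowSums(r1) == 200L))
  expect_true(all(r1 <= big))

  expect_error(rarefy(tab, 1e6), "no samples at depth")
})

test_that("rarefaction matches the exact hypergeometric mean", {
  tab <- matrix(c(10L, 10L), 1, 2, dimnames = list("s", c("a", "b")))
  draws <- vapply(1:2000, function(s) rarefy(tab, 10, seed = s)[1, 1],
                  integer(1))
  expect_true(all(draws + vapply(1:2000, function(s)
    rarefy(tab, 10, seed = s)[1, 2], integer(1)) == 10L))
  # mean of hypergeometric(N=20, K=10, n=10) is 5; se over 2000 seeds ~0.026
  expect_lt(abs(mean(draws) - 5), 0.15)
})

test_that("observed features counts positives and ignores column order", {
  tab <- rbind(a = c(5, 0, 3), b = c(0, 0, 0), c = c(1, 2, 3))
  colnames(tab) <- c("x", "y", "z")
  expect_identical(unname(observed_features(tab)), c(2L, 0L, 3L))
  perm <- tab[, c(3, 1, 2)]
  expect_identical(observed_features(perm), observed_features(tab))
})

test_that("age-bin joining unions presence within subject and bins correctly", {
  tab <- rbind(s1 = c(5L, 5L, 0L), s2 = c(0L, 5L, 5L), s3 = c(10L, 0L, 0L))
  colnames(tab) <- c("a", "b", "c")
  rec <- make_records(c("s1", "s2", "s3"), c("S1", "S1", "S2"),
                      c(10, 11, 12), c("daycare", "daycare", "homecare"),
                      facility = c("A", "A", NA), class_id = c("A1", "A1", NA),
                      timepoint = c(1, 2, NA))
  out <- bin_alpha_by_age(tab, rec, bin_width_months = 5)
  # S1's two samples fall in the 10-15 bin: union {a,b} and {b,c} -> 3
  expect_equal(out$alpha[out$subject_id == "S1"], 3L)
  # at most one value per (subject, bin)
  expect_false(anyDuplicated(out[, c("subject_id", "bin")]) > 0)
  # single-sample subjects keep their own alpha
  expect_equal(out$alpha[out$subject_id == "S2"], 1L)
})

test_that("per-bin comparison detects a planted richness difference", {
  # planted higher richness in day care within each bin; direction should be
  # recovered in essentially every replicate
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    set.seed(s)
    n <- 15L
    alpha_dc <- rnorm(n, mean = 120, sd = 6)
    alpha_hc <- rnorm(n, mean = 100, sd = 6)
    tst <- mann_whitney(alpha_dc, alpha_hc, alternative = "two_sided")
    ok <- tst$p_value < 0.05 && median(alpha_dc) > median(alpha_hc)
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})
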