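test_that("pairwise age matching is exhaustive within the gap", {
  rec <- make_records(c("a", "b", "c"), c("S1", "S2", "S3"),
                      c(10.0, 10.5, 12.0), "daycare",
                      facility = c("A", "A", "B"),
                      class_id = c("A1", "A1", "B1"), timepoint = 1)
  pr <- pairwise_age_match(rec, 1, max_gap = 1.0)
  expect_equal(nrow(pr), 1L)                       # only (10.0, 10.5) fits
  expect_setequal(c(pr$sample_a, pr$sample_b), c("a", "b"))

  same_age <- make_records(c("a", "b", "c"), c("S1", "S2", "S3"),
                           10, "daycare", facility = c("A", "A", "B"),
                           class_id = c("A1", "A1", "B1"), timepoint = 1)
  pr2 <- pairwise_age_match(same_age, 1)
  expect_equal(nrow(pr2), 3L)
  expect_equal(sort(pr2$same_group), c(FALSE, FALSE, TRUE))
})

test_that("pairwise age matching equals the brute-force double loop", {
  set.seed(42)
  n <- 40
  rec <- make_records(paste0("s", 1:n), paste0("S", 1:n),
                      round(runif(n, 8, 24), 2), "daycare",
                      facility = sample(LETTERS[1:4], n, TRUE),
                      class_id = sample(paste0("C", 1:6), n, TRUE),
                      timepoint = 2)
  pr <- pairwise_age_match(rec, 2, max_gap = 1.0)
  # independent brute force over the full double loop
  expected <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(rec$age_months[i] - rec$age_months[j]) <= 1.0) {
      expected <- expected + 1L
      key <- paste(sort(c(rec$sample_id[i], rec$sample_id[j])), collapse = "|")
      got <- paste(sort(c(pr$sample_a, pr$sample_b)[c(
        which(pr$sample_a == rec$sample_id[i] & pr$sample_b == rec$sample_id[j]),
        which(pr$sample_b == rec$sample_id[i] & pr$sample_a == rec$sample_id[j]))]),
        collapse = "|")
      expect_true(nchar(got) > 0, label = paste("pair", key, "present"))
    }
  }
  expect_equal(nrow(pr), expected)

  # order stability: shuffling metadata rows leaves the pair set unchanged
  shuf <- rec[sample(n), ]
  pr_shuf <- pairwise_age_match(shuf, 2, max_gap = 1.0)
  norm <- function(p) {
    k <- apply(cbind(pmin(p$sample_a, p$sample_b),
                     pmax(p$sample_a, p$sample_b)), 1, paste, collapse = "|")
    sort(k)
  }
  expect_identical(norm(pr_shuf), norm(pr))
})

test_that("greedy anchor matching picks the latest eligible timepoint, strictly", {
  rec <- rbind(
    make_records("h1", "H1", 12.0, "homecare"),
    make_records(c("d1.t1", "d1.t2"), "D1", c(11.5, 12.4), "daycare",
                 facility = "A", class_id = "A1", timepoint = c(1, 2)))
  g <- greedy_anchor_match(rec, max_gap = 1.0)
  expect_identical(g$member, "d1.t2")              # latest eligible wins

  # exactly 1.0 month apart is excluded under the strict window
  rec2 <- rbind(make_records("h1", "H1", 12.0, "homecare"),
                make_records("d1.t1", "D1", 13.0, "daycare",
                             facility = "A", class_id = "A1", timepoint = 1))
  expect_error(suppressMessages(greedy_anchor_match(rec2, max_gap = 1.0)),
               "no anchor")
  g2 <- greedy_anchor_match(rec2, max_gap = 1.0, strict = FALSE)
  expect_identical(g2$member, "d1.t1")
})

test_that("greedy anchor matching satisfies the post-hoc validity oracle", {
  set.seed(7)
  n_dc <- 30
  dc <- do.call(rbind, lapply(seq_len(n_dc), function(i) {
    entry <- runif(1, 8, 20)
    tps <- sort(sample(1:5, sample(2:5, 1)))
    make_records(sprintf("d%02d.t%d", i, tps), sprintf("D%02d", i),
                 entry + c(0, 2, 4, 7, 10)[tps], "daycare",
                 facility = "A", class_id = "A1", timepoint = tps)
  }))
  hc <- make_records(sprintf("h%02d", 1:10), sprintf("H%02d", 1:10),
                     runif(10, 9, 22), "homecare")
  rec <- rbind(dc, hc)
  g <- suppressMessages(greedy_anchor_match(rec, max_gap = 1.0))

  member_subject <- rec$subject_id[match(g$member, rec$sample_id)]
  expect_false(anyDuplicated(member_subject) > 0)  # one sample per daycare child
  expect_true(all(g$age_gap < 1.0))                # strict gap bound

  # maximality: every unassigned daycare child has no sample eligible for
  # any anchor under the sweep rule
  pool <- dc[!dc$subject_id %in% member_subject, , drop = FALSE]
  anchors_age <- hc$age_months
  if (nrow(pool)) {
    gaps <- outer(pool$age_months, anchors_age,
                  function(a, b) abs(a - b))
    expect_true(all(gaps >= 1.0))
  }

  # order stability: shuffled input rows give the same assignment
  g_shuf <- suppressMessages(greedy_anchor_match(rec[sample(nrow(rec)), ],
                                                 max_gap = 1.0))
  expect_identical(g_shuf, g)
})

test_that("random matched subsets are reproducible, sized, and bounded", {
  members <- sprintf("m%02d", 1:60)
  s1 <- random_matched_subsets(members, k = 24, n_subsets = 100, seed = 3)
  s2 <- random_matched_subsets(members, k = 24, n_subsets = 100, seed = 3)
  s3 <- random_matched_subsets(members, k = 24, n_subsets = 100, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(vapply(s1, length, integer(1)) == 24L))
  expect_true(all(vapply(s1, anyDuplicated, integer(1)) == 0L))

  full <- random_matched_subsets(members[1:24], k = 24, n_subsets = 5, seed = 1)
  expect_true(all(vapply(full, function(x) setequal(x, members[1:24]),
                         logical(1))))
  expect_error(random_matched_subsets(members[1:10], k = 24), "exceeds")
})
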