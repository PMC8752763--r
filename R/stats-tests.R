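# Rank and permutation tests.
#
# Every permutation p-value uses the add-one convention
# p = (#{null >= observed} + 1) / (n_perm + 1), so p >= 1/(n_perm + 1).

test_result <- function(statistic, p_value, alternative,
                        n_permutations = NULL, method = "") {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 alternative = alternative, n_permutations = n_permutations,
                 method = method),
            class = "daybiome_test")
}

#' @export
print.daybiome_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), " (", x$alternative, ")", sep = "")
  if (!is.null(x$n_permutations)) cat(", permutations =", x$n_permutations)
  cat("\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: exact enumeration when both samples are
#' small (|x|*|y| <= 400) and tie-free, otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y numeric value vectors (each non-empty).
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return a `daybiome_test` with the U statistic of `x`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_db("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                           alternative = sub("two_sided", "two.sided", alternative))
  test_result(wt$statistic, wt$p.value, alternative,
              method = if (exact) "Mann-Whitney (exact)" else
                "Mann-Whitney (normal approximation, tie-corrected)")
}

#' Permutation Spearman rank correlation
#'
#' Spearman rho with mid-ranks for ties; the p-value is computed by
#' permuting `y` against `x`, two-sided on |rho| by default.
#'
#' @param x,y aligned numeric vectors, length >= 3.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return a `daybiome_test` with `statistic` = rho.
#' @export
spearman_perm <- function(x, y, n_perm = 1000, seed = 0,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n != length(y) || n < 3L) stop_db("x and y must be aligned, length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_db("rho undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(rx, ry[sample.int(n)])
  }, numeric(1L)))
  hits <- switch(alternative,
                 two_sided = sum(abs(null) >= abs(rho)),
                 greater = sum(null >= rho),
                 less = sum(null <= rho))
  test_result(rho, (hits + 1) / (n_perm + 1), alternative,
              n_permutations = n_perm, method = "Spearman rank correlation (permutation)")
}

#' Slope-equality permutation test
#'
#' Tests whether the ordinary-least-squares slope of `y` on `x` in group 1
#' exceeds that of group 2 (for alpha-diversity trajectories: whether
#' richness accrues faster in one care setting). The statistic is
#' `b1 - b2`; the null is built by permuting group labels over the pooled
#' points, preserving group sizes. Permutations producing a constant-`x`
#' group are redrawn (and logged).
#'
#' @param x1,y1 numeric vectors for group 1 (>= 3 points).
#' @param x2,y2 numeric vectors for group 2 (>= 3 points).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"greater"` (b1 > b2, default), `"less"` or
#'   `"two_sided"`.
#' @return a `daybiome_test`; `statistic` is the observed slope difference.
#' @export
slope_equality_perm <- function(x1, y1, x2, y2, n_perm = 1000, seed = 0,
                                alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(x1) < 3L || length(x2) < 3L) stop_db("each group needs >= 3 points")
  slope <- function(x, y) {
    v <- stats::var(x)
    if (v == 0) return(NA_real_)
    stats::cov(x, y) / v
  }
  obs <- slope(x1, y1) - slope(x2, y2)
  if (is.na(obs)) stop_db("degenerate (constant) x in an observed group")
  px <- c(x1, x2)
  py <- c(y1, y2)
  n1 <- length(x1)
  n <- length(px)
  redraws <- 0L
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    repeat {
      idx <- sample.int(n)
      s <- slope(px[idx[seq_len(n1)]], py[idx[seq_len(n1)]]) -
        slope(px[idx[-seq_len(n1)]], py[idx[-seq_len(n1)]])
      if (!is.na(s)) return(s)
      redraws <<- redraws + 1L
    }
  }, numeric(1L)))
  if (redraws > 0L) db_log("slope_equality_perm: redrew ", redraws,
                           " degenerate permutation(s)")
  hits <- switch(alternative,
                 greater = sum(null >= obs),
                 less = sum(null <= obs),
                 two_sided = sum(abs(null) >= abs(obs)))
  test_result(obs, (hits + 1) / (n_perm + 1), alternative,
              n_permutations = n_perm, method = "slope-equality permutation test")
}

#' Chi-square test of overlap between two feature sets
#'
#' Cross-tabulates membership in `query_set` against membership in
#' `reference_set` over `universe` and applies the Pearson chi-square test
#' with 1 df (no continuity correction). Feature identity is exact id
#' (sequence) equality, which is what makes ASV sets comparable across
#' studies.
#'
#' @param query_set,reference_set character vectors of feature ids, subsets
#'   of `universe`.
#' @param universe character vector of all feature ids considered.
#' @return list with `test` (a `daybiome_test`, statistic = chi-square) and
#'   `table` (the 2x2 contingency table).
#' @export
set_overlap_chi2 <- function(query_set, reference_set, universe) {
  if (!length(universe)) stop_db("empty universe")
  if (length(setdiff(query_set, universe)) ||
      length(setdiff(reference_set, universe))) {
    stop_db("query and reference sets must be subsets of the universe")
  }
  in_q <- factor(universe %in% query_set, levels = c(TRUE, FALSE),
                 labels = c("in_query", "out_query"))
  in_r <- factor(universe %in% reference_set, levels = c(TRUE, FALSE),
                 labels = c("in_reference", "out_reference"))
  tab <- table(in_q, in_r)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = test_result(ct$statistic, ct$p.value, "two_sided",
                          method = "Pearson chi-square (1 df) set overlap"),
       table = tab)
}

#' Correlation of a per-sample value with age, one random sample per child
#'
#' Longitudinal designs repeat subjects; this repeats a Spearman correlation
#' (e.g. PC1 vs. age) over random draws of one sample per child, returning
#' the rho distribution so subject pseudo-replication never inflates a
#' single correlation estimate.
#'
#' @param values named numeric vector (names are sample ids), e.g. PC1
#'   coordinates.
#' @param records metadata data.frame covering those samples.
#' @param n_iter number of random draws (default 100).
#' @param seed integer seed.
#' @return list with `iterations` (data.frame `rho`, `p_value`) and
#'   `summary` (mean, sd, min, max of rho).
#' @export
per_child_subsample_correlation <- function(values, records, n_iter = 100,
                                            seed = 0) {
  records <- records[records$sample_id %in% names(values), , drop = FALSE]
  subjects <- split(records$sample_id, records$subject_id)
  if (length(subjects) < 3L) stop_db("need at least 3 children")
  iters <- with_seed(seed, lapply(seq_len(n_iter), function(i) {
    picked <- vapply(subjects, function(s)
      if (length(s) == 1L) s else sample(s, 1L), character(1L))
    age <- records$age_months[match(picked, records$sample_id)]
    ct <- suppressWarnings(stats::cor.test(values[picked], age,
                                           method = "spearman"))
    c(rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  df <- as.data.frame(do.call(rbind, iters))
  list(iterations = df,
       summary = c(mean = mean(df$rho), sd = stats::sd(df$rho),
                   min = min(df$rho), max = max(df$rho)))
}
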