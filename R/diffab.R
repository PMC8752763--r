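# Paired rank-mean permutation differential abundance and discrete FDR.
#
# The test statistic per feature is the difference in mean rank of relative
# abundance between the two labels; the null is built by shuffling labels
# only within anchor groups (each group = one home-care sample plus its
# age-matched day-care samples), which preserves the age matching. The same
# permutation stream is applied jointly to every feature, which is what the
# discrete FDR estimate requires.

#' Paired rank-mean permutation test (per feature)
#'
#' Ranks each feature's relative abundance across all samples (mid-ranks on
#' ties; zeros share the lowest ranks, which matters for sparse features)
#' and compares mean ranks between labels; significance comes from label
#' permutations constrained within groups.
#'
#' @param table matrix, samples x features. Rows are fraction-normalized
#'   internally (each row divided by its sum), so counts or relative
#'   abundances are both accepted.
#' @param labels binary per-sample labels (0/1, logical, or a two-level
#'   factor; label 1 / second level is the "positive" direction).
#' @param groups per-sample group ids defining the permutation blocks (e.g.
#'   the anchor of the matched group). Groups containing a single sample are
#'   excluded with a warning; single-label groups are kept (they contribute
#'   no signal) and logged.
#' @param n_perm number of joint permutations (default 1000).
#' @param seed integer seed.
#' @return list with `feature_id`, `statistic` (observed mean-rank delta,
#'   label1 - label0), `p_value` (two-sided, add-one), `null` (n_perm x
#'   features matrix of null statistics, for [dsfdr()]), `n_samples`.
#' @export
rank_mean_paired_test <- function(table, labels, groups, n_perm = 1000, seed = 0) {
  if (n_perm < 1L) stop_db("n_perm must be >= 1")
  lab <- as.integer(as.factor(labels)) - 1L
  if (!all(lab %in% c(0L, 1L)) || length(unique(lab)) != 2L) {
    stop_db("labels must be binary with both levels present")
  }
  groups <- as.character(groups)
  stopifnot(length(lab) == nrow(table), length(groups) == nrow(table))
  gsize <- table(groups)
  singletons <- names(gsize)[gsize == 1L]
  if (length(singletons)) {
    warning("excluding ", length(singletons), " single-sample group(s)")
    keep <- !groups %in% singletons
    table <- table[keep, , drop = FALSE]
    lab <- lab[keep]
    groups <- groups[keep]
  }
  single_label <- vapply(split(lab, groups), function(l) length(unique(l)) == 1L,
                         logical(1L))
  if (any(single_label)) {
    db_log("rank_mean_paired_test: ", sum(single_label),
           " single-label group(s) contribute no signal")
  }
  nz <- colSums(table) > 0
  if (any(!nz)) {
    db_log("rank_mean_paired_test: dropping ", sum(!nz), " all-zero feature(s)")
  }
  table <- table[, nz, drop = FALSE]
  frac <- table / pmax(rowSums(table), .Machine$double.eps)
  n <- nrow(frac)
  ranks <- apply(frac, 2L, rank)  # mid-ranks; zeros tie at the bottom
  n1 <- sum(lab == 1L)
  n0 <- n - n1
  w_of <- function(l) l / n1 - (1 - l) / n0
  obs <- drop(w_of(lab) %*% ranks)
  gidx <- split(seq_len(n), groups)
  perm_w <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      pl <- lab
      for (ix in gidx) pl[ix] <- pl[ix][sample.int(length(ix))]
      w_of(pl)
    }, numeric(n)))
  })
  null <- perm_w %*% ranks          # n_perm x features
  p <- (colSums(abs(null) >= matrix(abs(obs), n_perm, ncol(ranks), byrow = TRUE)) + 1) /
    (n_perm + 1)
  list(feature_id = colnames(table), statistic = unname(obs),
       p_value = unname(p), null = null, n_samples = n,
       n_permutations = n_perm)
}

#' Discrete FDR (dsFDR) control from joint permutations
#'
#' Estimates, for each candidate threshold `t` on the absolute statistic,
#' \deqn{\widehat{FDR}(t) = \frac{\mathrm{mean}_b\, \#\{f: |s^{null}_{bf}|
#' \ge t\}}{\max(1, \#\{f: |s_f| \ge t\})}}
#' and rejects every feature at or above the smallest threshold whose
#' estimated FDR is at most `alpha`. The null statistics must come from the
#' same joint permutations across features (as produced by
#' [rank_mean_paired_test()]), which is what adapts the estimate to the
#' discreteness of sparse count data. A feature's q-value is the minimum
#' estimated FDR over thresholds at or below its own statistic; by
#' construction the rejection set is downward-closed in the statistic and
#' monotone in `alpha`.
#'
#' @param observed per-feature observed statistics.
#' @param null_perms matrix of null statistics, permutations x features.
#' @param alpha target FDR (default 0.1).
#' @return list with `rejected` (logical per feature), `q_value`,
#'   `threshold` (the accepted |statistic| cutoff, `Inf` if none).
#' @export
dsfdr <- function(observed, null_perms, alpha = 0.1) {
  if (is.null(dim(null_perms)) || nrow(null_perms) < 1L) {
    stop_db("null_perms must be a permutations x features matrix with >= 1 row")
  }
  if (ncol(null_perms) != length(observed)) {
    stop_db("null_perms must have one column per observed statistic")
  }
  s <- abs(observed)
  thresholds <- sort(unique(s[s > 0]), decreasing = FALSE)
  if (!length(thresholds)) {
    return(list(rejected = rep(FALSE, length(s)),
                q_value = rep(1, length(s)), threshold = Inf))
  }
  nulls <- sort(abs(as.vector(null_perms)))
  b <- nrow(null_perms)
  # mean over permutations of #{|null| >= t} = (#pooled nulls >= t) / b
  n_null_ge <- (length(nulls) - findInterval(thresholds - 1e-12, nulls)) / b
  obs_sorted <- sort(s)
  n_obs_ge <- length(s) - findInterval(thresholds - 1e-12, obs_sorted)
  fdr_t <- n_null_ge / pmax(1, n_obs_ge)
  ok <- fdr_t <= alpha
  threshold <- if (any(ok)) thresholds[which(ok)[1L]] else Inf
  # q(feature) = min estimated FDR over thresholds at or below its statistic:
  # running minimum from the smallest threshold up
  runmin <- cummin(fdr_t)
  pos <- findInterval(s + 1e-12, thresholds)
  q <- ifelse(pos >= 1L, pmin(1, runmin[pmax(pos, 1L)]), 1)
  list(rejected = s >= threshold, q_value = q, threshold = threshold)
}

#' Matched differential abundance between care settings
#'
#' Convenience wrapper tying the anchor matching to the paired rank-mean
#' test and dsFDR: builds the matched sample set from
#' [greedy_anchor_match()] output, labels day care as 1 and home care as 0,
#' groups by anchor, and reports per-feature results.
#'
#' @param table feature table (samples x features), counts or fractions.
#' @param records metadata data.frame.
#' @param anchor_groups data.frame from [greedy_anchor_match()].
#' @param alpha target FDR (default 0.1).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param correction `"dsfdr"` (default) or `"BH"` — Benjamini-Hochberg on
#'   the permutation p-values, offered as a conventional alternative; note
#'   that permutation p-values are floored at 1/(n_perm+1), which limits BH
#'   resolution for large feature sets.
#' @return data.frame with `feature_id`, `rank_mean_delta`, `p_value`,
#'   `q_value`, `rejected`, `direction` (`"daycare"`/`"homecare"`).
#' @export
diff_abundance <- function(table, records, anchor_groups, alpha = 0.1,
                           n_perm = 1000, seed = 0,
                           correction = c("dsfdr", "BH")) {
  correction <- match.arg(correction)
  ids <- c(anchor_groups$anchor, anchor_groups$member)
  grp <- c(anchor_groups$anchor, anchor_groups$anchor)
  keep <- !duplicated(ids)
  ids <- ids[keep]
  grp <- grp[keep]
  sub <- table[ids, , drop = FALSE]
  setting <- records$care_setting[match(ids, records$sample_id)]
  res <- rank_mean_paired_test(sub, labels = setting == "daycare",
                               groups = grp, n_perm = n_perm, seed = seed)
  fdr <- if (correction == "dsfdr") {
    dsfdr(res$statistic, res$null, alpha = alpha)
  } else {
    q <- stats::p.adjust(res$p_value, method = "BH")
    list(q_value = q, rejected = q <= alpha)
  }
  data.frame(feature_id = res$feature_id,
             rank_mean_delta = res$statistic,
             p_value = res$p_value,
             q_value = fdr$q_value,
             rejected = fdr$rejected,
             direction = ifelse(res$statistic >= 0, "daycare", "homecare"),
             stringsAsFactors = FALSE)
}

#' Write differential-abundance results as TSV
#'
#' @param result data.frame from [diff_abundance()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diffab <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export matched input tables for external multivariable modeling
#'
#' Writes the fraction-normalized feature table and metadata of the matched
#' samples in the layout multivariable association tools (e.g. linear-model
#' pipelines with subject random effects) expect, marking the boundary of
#' what this package models itself.
#'
#' @param table feature table (samples x features).
#' @param records metadata data.frame.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
export_multivariable_input <- function(table, records, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  frac <- table / pmax(rowSums(table), 1L)
  utils::write.table(data.frame(sample_id = rownames(frac), frac,
                                check.names = FALSE),
                     file.path(directory, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(records, file.path(directory, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(directory)
}
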