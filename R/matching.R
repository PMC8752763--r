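# Age-matched pair construction and greedy home-care-anchor matching.
#
# Both procedures exist to remove the age confounder before comparing care
# settings or facilities: microbial composition changes quickly with age in
# the second and third year of life, so unmatched group comparisons mostly
# measure age structure.

#' All age-matched pairs of day-care children at one sampling point
#'
#' Restricts to day-care samples at `timepoint` (one sample per child by the
#' metadata invariant) and returns every unordered pair of distinct children
#' whose ages differ by at most `max_gap` months, labeled `same_group` by
#' facility or by class.
#'
#' @param records metadata data.frame.
#' @param timepoint sampling point (1-5).
#' @param max_gap maximum age gap in months, inclusive (default 1).
#' @param group_by `"facility"` or `"class_id"`: which label defines
#'   `same_group`.
#' @return data.frame with columns `sample_a`, `sample_b`, `timepoint`,
#'   `age_gap`, `same_group`.
#' @export
pairwise_age_match <- function(records, timepoint, max_gap = 1.0,
                               group_by = c("facility", "class_id")) {
  group_by <- match.arg(group_by)
  r <- records[records$care_setting == "daycare" &
                 !is.na(records$timepoint) & records$timepoint == timepoint, ,
               drop = FALSE]
  empty <- data.frame(sample_a = character(), sample_b = character(),
                      timepoint = integer(), age_gap = numeric(),
                      same_group = logical(), stringsAsFactors = FALSE)
  if (nrow(r) < 2L) {
    warning("fewer than 2 eligible daycare samples at timepoint ", timepoint)
    return(empty)
  }
  idx <- utils::combn(nrow(r), 2L)
  gap <- abs(r$age_months[idx[1L, ]] - r$age_months[idx[2L, ]])
  keep <- gap <= max_gap & r$subject_id[idx[1L, ]] != r$subject_id[idx[2L, ]]
  if (!any(keep)) return(empty)
  data.frame(sample_a = r$sample_id[idx[1L, keep]],
             sample_b = r$sample_id[idx[2L, keep]],
             timepoint = as.integer(timepoint),
             age_gap = gap[keep],
             same_group = r[[group_by]][idx[1L, keep]] == r[[group_by]][idx[2L, keep]],
             stringsAsFactors = FALSE)
}

#' Greedy home-care-anchor matching
#'
#' Builds, for each home-care child (the anchor), a set of age-matched
#' day-care samples: repeated sweeps over home-care children in a fixed,
#' documented order (sorted by `subject_id`); on each visit, among day-care
#' children remaining in the pool whose latest eligible time point lies
#' strictly within `max_gap` months of the anchor's age, the candidate with
#' the smallest age gap (ties by `subject_id`) is assigned and all samples of
#' that child leave the pool. Sweeps repeat until a full sweep assigns
#' nothing. Each day-care child therefore contributes at most one sample
#' overall, which removes dependence between a child's longitudinal samples.
#'
#' @param records metadata data.frame containing both care settings.
#' @param max_gap age window in months; strict (`<`) by default, matching the
#'   procedure's phrasing, switchable via `strict`.
#' @param strict logical; if `FALSE`, the window is `<=` `max_gap`.
#' @return data.frame with one row per (anchor, member): columns `anchor`
#'   (home-care sample id), `member` (day-care sample id), `age_gap`,
#'   `member_timepoint`. Anchors with no eligible match are omitted and
#'   logged.
#' @export
greedy_anchor_match <- function(records, max_gap = 1.0, strict = TRUE) {
  hc <- records[records$care_setting == "homecare", , drop = FALSE]
  dc <- records[records$care_setting == "daycare", , drop = FALSE]
  if (!nrow(hc) || !nrow(dc)) stop_db("need samples from both care settings")
  anchors <- hc[order(hc$subject_id), , drop = FALSE]
  # one anchor sample per home-care child (single-sample design; if several,
  # keep the first by sample_id for determinism)
  anchors <- anchors[!duplicated(anchors$subject_id), , drop = FALSE]
  pool <- dc
  within <- if (strict) function(g) g < max_gap else function(g) g <= max_gap
  out <- list()
  repeat {
    assigned_this_sweep <- FALSE
    for (i in seq_len(nrow(anchors))) {
      a <- anchors[i, ]
      if (!nrow(pool)) break
      gap <- abs(pool$age_months - a$age_months)
      elig <- within(gap)
      if (!any(elig)) next
      cand <- pool[elig, , drop = FALSE]
      cand$gap <- gap[elig]
      # latest eligible time point of each remaining child
      cand <- cand[order(cand$subject_id, -cand$timepoint), , drop = FALSE]
      cand <- cand[!duplicated(cand$subject_id), , drop = FALSE]
      cand <- cand[order(cand$gap, cand$subject_id), , drop = FALSE]
      pick <- cand[1L, ]
      out[[length(out) + 1L]] <- data.frame(
        anchor = a$sample_id, member = pick$sample_id, age_gap = pick$gap,
        member_timepoint = pick$timepoint, stringsAsFactors = FALSE)
      pool <- pool[pool$subject_id != pick$subject_id, , drop = FALSE]
      assigned_this_sweep <- TRUE
    }
    if (!assigned_this_sweep) break
  }
  if (!length(out)) stop_db("no anchor acquired any age-matched daycare sample")
  res <- do.call(rbind, out)
  unmatched <- setdiff(anchors$sample_id, res$anchor)
  if (length(unmatched)) {
    db_log("greedy_anchor_match: no eligible match for anchor(s): ",
           paste(unmatched, collapse = ", "))
  }
  res <- res[order(res$anchor, res$member), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Random matched subsets of day-care children
#'
#' Uniform without-replacement subsets of size `k` from a pool of matched
#' day-care samples (one sample per child), reproducible by seed. Used to
#' show a matched-subset classifier result is not an artifact of one
#' particular manual matching.
#'
#' @param members character vector of day-care sample ids, one per child.
#' @param k subset size (default 24).
#' @param n_subsets number of subsets (default 100).
#' @param seed integer seed.
#' @return list of `n_subsets` character vectors of length `k`.
#' @export
random_matched_subsets <- function(members, k = 24, n_subsets = 100, seed = 0) {
  if (k > length(members)) {
    stop_db("k (", k, ") exceeds the number of available members (",
            length(members), ")")
  }
  with_seed(seed, lapply(seq_len(n_subsets), function(i) sample(members, k)))
}

#' Write matched pairs / anchor groups as TSV
#'
#' @param pairs output of [pairwise_age_match()].
#' @param groups output of [greedy_anchor_match()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
write_anchor_groups <- function(groups, path) {
  agg <- stats::aggregate(member ~ anchor, groups,
                          function(m) paste(m, collapse = ","))
  utils::write.table(agg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
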