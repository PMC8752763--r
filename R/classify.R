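# Matched-subset classification protocol: balanced age-matched groups,
# repeated classifier evaluation on out-of-bag scores, ROC AUC and the
# Youden threshold. The protocol is the point; the learner is a pluggable
# contract with a bagged-trees default.

#' ROC AUC from scores and binary labels
#'
#' The probability that a random positive outscores a random negative, ties
#' counted one half (the trapezoidal ROC area, and algebraically
#' U / (n1 * n2) of the Mann-Whitney statistic on the same data).
#'
#' @param scores numeric per-sample scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or two-level factor; the
#'   second level is positive).
#' @return the AUC, a value in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  lab <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop_db("both classes must be present")
  r <- rank(scores)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index threshold and confusion counts
#'
#' Scans the observed scores as cut-points (predict positive when
#' `score >= threshold`) and returns the cut maximizing
#' sensitivity + specificity - 1; ties are broken toward the lower
#' threshold.
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `youden`, and confusion counts `tp`,
#'   `tn`, `fp`, `fn` at the threshold.
#' @export
youden_threshold <- function(scores, labels) {
  lab <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop_db("both classes must be present")
  cuts <- sort(unique(scores))
  j <- vapply(cuts, function(t) {
    sens <- sum(scores >= t & lab == 1L) / n1
    spec <- sum(scores < t & lab == 0L) / n0
    sens + spec - 1
  }, numeric(1L))
  best <- cuts[which.max(j)]  # which.max takes the first (lowest) on ties
  list(threshold = best, youden = max(j),
       tp = sum(scores >= best & lab == 1L),
       tn = sum(scores < best & lab == 0L),
       fp = sum(scores >= best & lab == 0L),
       fn = sum(scores < best & lab == 1L))
}

#' Default out-of-bag classifier: bagged trees
#'
#' Wraps [randomForest::randomForest()]; the returned out-of-bag vote
#' fraction for the positive class is an internal held-out score (each
#' sample is scored only by trees that did not draw it), so no separate
#' split is needed. Trees are grown on class-stratified bootstrap samples
#' (per-class in-bag counts fixed at the class sizes): with few dozen
#' samples, plain bootstrapping makes the in-bag class prior shift away
#' from each out-of-bag sample's own class, which biases null out-of-bag
#' scores below chance; fixing the per-class counts removes that prior
#' shift. Other learner settings follow the library defaults.
#'
#' @param x numeric feature matrix (training samples x features).
#' @param y two-level factor of labels.
#' @param seed integer seed for the forest.
#' @return list with `oob_scores`: per-training-sample positive-class
#'   probability in \[0, 1\], and `importance`: per-feature mean decrease in
#'   Gini, decreasing.
#' @export
rf_oob_classifier <- function(x, y, seed = 0) {
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, strata = y, sampsize = as.vector(table(y)), replace = TRUE))
  imp <- drop(fit$importance[, 1L])
  list(oob_scores = unname(fit$votes[, levels(y)[2L]]),
       importance = sort(imp, decreasing = TRUE))
}

#' Matched-subset classifier evaluation
#'
#' The balanced-design evaluation protocol: for each random subset of `k`
#' day-care children from `pool` (one sample per child), fit the classifier
#' on the `2k` samples (subset + the `k` home-care anchors), collect
#' out-of-bag positive-class scores, and compute the ROC AUC. With
#' `n_subsets = 1` and `pool` of size `k` this is the single manually
#' matched evaluation. Features are the relative abundances of every
#' feature present in at least one training sample; there is no feature
#' selection.
#'
#' @param table feature table (samples x features), counts or fractions.
#' @param records metadata data.frame.
#' @param pool character vector of day-care sample ids (one per child).
#' @param anchors character vector of home-care sample ids; the group sizes
#'   are equalized by design, so `length(anchors)` must equal `k`.
#' @param k day-care subset size (default 24).
#' @param n_subsets number of random subsets (default 100).
#' @param classifier a function `(x, y, seed) -> list(oob_scores = ...)`;
#'   default [rf_oob_classifier()]. If it returns no `oob_scores` and
#'   `fallback_cv` is `FALSE`, an error instructs enabling the
#'   cross-validated fallback.
#' @param fallback_cv if `TRUE`, classifiers without out-of-bag scores are
#'   evaluated by 5-fold cross-validated scores instead.
#' @param seed integer seed (drives subset draws and per-fit classifier
#'   seeds).
#' @return list with `auc` (per-subset numeric vector), `summary` (min,
#'   median, max), `youden` (threshold + confusion of the median-AUC
#'   subset's scores), `scores` and `labels` of that subset.
#' @export
matched_subset_evaluation <- function(table, records, pool, anchors, k = 24,
                                      n_subsets = 100,
                                      classifier = rf_oob_classifier,
                                      fallback_cv = FALSE, seed = 0) {
  if (length(anchors) != k) {
    stop_db("length(anchors) must equal k (balanced design)")
  }
  subsets <- random_matched_subsets(pool, k = k, n_subsets = n_subsets,
                                    seed = seed)
  frac <- table / pmax(rowSums(table), 1L)
  setting <- records$care_setting[match(rownames(frac), records$sample_id)]
  evals <- lapply(seq_along(subsets), function(i) {
    ids <- c(anchors, subsets[[i]])
    x <- frac[ids, , drop = FALSE]
    x <- x[, colSums(x) > 0, drop = FALSE]
    y <- factor(setting[match(ids, rownames(frac))],
                levels = c("homecare", "daycare"))
    fit <- classifier(x, y, seed = seed * 1000L + i)
    scores <- fit$oob_scores
    if (is.null(scores)) {
      if (!fallback_cv) {
        stop_db("classifier provides no out-of-bag scores; ",
                "set fallback_cv = TRUE to use cross-validated scores")
      }
      scores <- cv_scores(x, y, classifier, seed = seed * 1000L + i)
    }
    list(auc = roc_auc(scores, y), scores = scores, labels = y)
  })
  aucs <- vapply(evals, `[[`, numeric(1L), "auc")
  med <- order(aucs)[ceiling(length(aucs) / 2)]
  list(auc = aucs,
       summary = c(min = min(aucs), median = stats::median(aucs), max = max(aucs)),
       youden = youden_threshold(evals[[med]]$scores, evals[[med]]$labels),
       scores = evals[[med]]$scores,
       labels = evals[[med]]$labels)
}

# 5-fold cross-validated positive-class scores for contracts without OOB.
cv_scores <- function(x, y, classifier, seed, folds = 5L) {
  n <- nrow(x)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- classifier(x[!test, , drop = FALSE], droplevels(y[!test]),
                      seed = seed + f)
    pred <- fit$predict
    if (is.null(pred)) {
      stop_db("cross-validated fallback requires the classifier to return ",
              "a 'predict' function")
    }
    scores[test] <- pred(x[test, , drop = FALSE])
  }
  scores
}
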