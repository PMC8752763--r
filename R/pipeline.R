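# End-to-end orchestration. Stages communicate through TSV files in the
# output directory so any stage can be re-run independently; the run config
# is serialized alongside the outputs (with its hash stamped into the
# summary) for provenance.

#' Build a run configuration
#'
#' @param feature_table path to the feature-table TSV (or `NULL` when a
#'   cohort bundle is passed to [run_full_analysis()] directly).
#' @param metadata path to the metadata TSV.
#' @param tree optional path to a rooted newick tree (required for the
#'   `"unifrac"` metric).
#' @param output_dir output directory.
#' @param orientation feature-table orientation, see [read_feature_table()].
#' @param rarefaction_depth,rarefaction_seed rarefaction settings.
#' @param distance_metric `"jaccard"`, `"bray_curtis"` or `"unifrac"`.
#' @param pair_max_gap,pair_group_by per-timepoint pair-matching settings.
#' @param anchor_max_gap,anchor_strict anchor-matching window.
#' @param n_perm feature-wise / PERMANOVA permutation count.
#' @param alpha target FDR for differential abundance.
#' @param permanova_terms ordered terms for the longitudinal variance
#'   partition.
#' @param classifier_k,classifier_subsets matched-subset classification
#'   settings.
#' @param bin_width_months alpha-diversity age-bin width.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list, validated.
#' @export
run_config <- function(feature_table = NULL, metadata = NULL, tree = NULL,
                       output_dir = "daybiome_out",
                       orientation = "samples_rows",
                       rarefaction_depth = 4000, rarefaction_seed = 0,
                       distance_metric = c("jaccard", "bray_curtis", "unifrac"),
                       pair_max_gap = 1.0, pair_group_by = "facility",
                       anchor_max_gap = 1.0, anchor_strict = TRUE,
                       n_perm = 1000, alpha = 0.1,
                       permanova_terms = c("age_months", "sex", "subject_id"),
                       classifier_k = 24, classifier_subsets = 100,
                       bin_width_months = 5, seed = 0) {
  cfg <- as.list(environment())
  cfg$distance_metric <- match.arg(distance_metric)
  if (cfg$distance_metric == "unifrac" && is.null(cfg$tree)) {
    stop_db("distance_metric 'unifrac' requires a tree")
  }
  structure(cfg, class = "run_config")
}

#' Run the full matched-design analysis
#'
#' Executes, in order: rarefaction; alpha diversity with age-bin comparison
#' and the slope-equality test; beta-diversity distances and PCoA with the
#' per-child PC1-age correlation; per-timepoint age-matched pair
#' construction with same/different-group Mann-Whitney tests; variance
#' partitioning (longitudinal with subject strata, and per timepoint);
#' anchor matching and paired rank-mean differential abundance with dsFDR;
#' and matched-subset classification. Every stage writes a TSV into the
#' output directory and is summarized in `summary.txt`; a stage failure
#' aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param cohort optional in-memory `daybiome_cohort` (skips file input).
#' @return invisibly, a list of per-stage results (`rarefied`, `alpha`,
#'   `alpha_bins`, `slope_test`, `distance`, `pcoa`, `pc1_age`, `pairs`,
#'   `pair_tests`, `permanova_longitudinal`, `permanova_timepoint`,
#'   `anchor_groups`, `diffab`, `classification`).
#' @export
run_full_analysis <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  writeLines(yaml::as.yaml(unclass(config)), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    db_log(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_db("stage '", name, "' failed: ", conditionMessage(e),
              " [inputs snapshot: ", cfg_path, "]")
    })
  }
  out <- list()
  note("run config hash: ", cfg_hash)

  stage("input", {
    if (is.null(cohort)) {
      table <- read_feature_table(config$feature_table, config$orientation)
      records <- read_metadata(config$metadata)
    } else {
      table <- cohort$table
      records <- cohort$records
    }
    out$table <- table
    out$records <- records
  })
  records <- out$records

  stage("rarefy", {
    out$rarefied <- withCallingHandlers(
      rarefy(out$table, config$rarefaction_depth, config$rarefaction_seed),
      message = function(m) {
        log_lines <<- c(log_lines, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
  })
  rar <- out$rarefied
  rrec <- records[records$sample_id %in% rownames(rar), , drop = FALSE]
  note("rarefied: ", nrow(rar), " samples at depth ", config$rarefaction_depth)

  stage("alpha", {
    alpha <- observed_features(rar)
    binned <- bin_alpha_by_age(rar, rrec, config$bin_width_months)
    out$alpha <- alpha
    out$alpha_bins <- compare_alpha_bins(binned)
    dc <- rrec$care_setting == "daycare"
    out$slope_test <- slope_equality_perm(
      rrec$age_months[dc], alpha[rrec$sample_id[dc]],
      rrec$age_months[!dc], alpha[rrec$sample_id[!dc]],
      n_perm = config$n_perm, seed = config$seed + 1L)
    utils::write.table(out$alpha_bins,
                       file.path(config$output_dir, "alpha_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("alpha: ", nrow(out$alpha_bins), " age bins compared; slope delta = ",
       signif(out$slope_test$statistic, 3), ", p = ",
       signif(out$slope_test$p_value, 3))

  stage("distance", {
    out$distance <- switch(config$distance_metric,
      jaccard = binary_jaccard(rar),
      bray_curtis = bray_curtis(rar),
      unifrac = unweighted_unifrac(rar, ape::read.tree(config$tree)))
    write_distance_matrix(out$distance,
                          file.path(config$output_dir, "distance.tsv"))
  })
  note("distance: ", config$distance_metric, " on ", nrow(out$distance),
       " samples")

  stage("pcoa", {
    ord <- pcoa(out$distance)
    out$pcoa <- ord
    pc1 <- ord$coordinates[, 1L]
    out$pc1_age <- per_child_subsample_correlation(pc1, rrec, n_iter = 100,
                                                    seed = config$seed + 2L)
  })
  note("pcoa: PC1-age rho mean ", signif(out$pc1_age$summary["mean"], 3),
       " (range ", signif(out$pc1_age$summary["min"], 3), " to ",
       signif(out$pc1_age$summary["max"], 3), ")")

  stage("pair_matching", {
    tps <- sort(unique(stats::na.omit(rrec$timepoint)))
    pair_list <- lapply(tps, function(tp)
      pairwise_age_match(rrec, tp, config$pair_max_gap,
                         group_by = config$pair_group_by))
    names(pair_list) <- paste0("tp", tps)
    out$pairs <- do.call(rbind, pair_list)
    out$pair_tests <- do.call(rbind, lapply(pair_list, function(pr) {
      if (!nrow(pr) || !any(pr$same_group) || !any(!pr$same_group)) return(NULL)
      d_same <- pair_distances(out$distance, pr$sample_a[pr$same_group],
                               pr$sample_b[pr$same_group])
      d_diff <- pair_distances(out$distance, pr$sample_a[!pr$same_group],
                               pr$sample_b[!pr$same_group])
      tst <- mann_whitney(d_same, d_diff, alternative = "less")
      data.frame(timepoint = pr$timepoint[1L], n_same = length(d_same),
                 n_diff = length(d_diff),
                 median_same = stats::median(d_same),
                 median_diff = stats::median(d_diff),
                 p_value = tst$p_value)
    }))
    write_pairs(out$pairs, file.path(config$output_dir, "pairs.tsv"))
    utils::write.table(out$pair_tests,
                       file.path(config$output_dir, "pair_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("pairs: ", nrow(out$pairs), " age-matched pairs across timepoints")

  stage("permanova", {
    out$permanova_longitudinal <- variance_partition(
      out$distance, rrec,
      focal_terms = config$permanova_terms,
      covariates = c("age_months", "sex"),
      strata = "subject_id", n_perm = min(config$n_perm, 999),
      seed = config$seed + 3L)
    tps <- sort(unique(stats::na.omit(rrec$timepoint)))
    out$permanova_timepoint <- do.call(rbind, lapply(tps, function(tp) {
      sub <- rrec[!is.na(rrec$timepoint) & rrec$timepoint == tp, , drop = FALSE]
      if (length(unique(sub$facility)) < 2L || nrow(sub) < 10L) return(NULL)
      vp <- variance_partition(
        out$distance[sub$sample_id, sub$sample_id], sub,
        focal_terms = c("facility", "class_id"),
        covariates = c("age_months", "sex"),
        strata = NULL, n_perm = min(config$n_perm, 999),
        seed = config$seed + 30L + tp)
      cbind(timepoint = tp, vp)
    }))
    write_permanova(out$permanova_longitudinal,
                    file.path(config$output_dir, "permanova_longitudinal.tsv"))
    write_permanova(out$permanova_timepoint,
                    file.path(config$output_dir, "permanova_timepoint.tsv"))
  })
  note("permanova: longitudinal terms ",
       paste(config$permanova_terms, collapse = ", "))

  stage("anchor_matching", {
    out$anchor_groups <- greedy_anchor_match(records, config$anchor_max_gap,
                                              strict = config$anchor_strict)
    write_anchor_groups(out$anchor_groups,
                        file.path(config$output_dir, "anchor_groups.tsv"))
  })
  note("anchors: ", length(unique(out$anchor_groups$anchor)),
       " home-care anchors matched to ", nrow(out$anchor_groups),
       " day-care samples")

  stage("diffab", {
    out$diffab <- diff_abundance(out$table, records, out$anchor_groups,
                                  alpha = config$alpha,
                                  n_perm = config$n_perm,
                                  seed = config$seed + 4L)
    write_diffab(out$diffab, file.path(config$output_dir, "diffab.tsv"))
  })
  note("diffab: ", sum(out$diffab$rejected), " features at FDR ", config$alpha,
       " (", sum(out$diffab$rejected & out$diffab$direction == "daycare"),
       " day care, ",
       sum(out$diffab$rejected & out$diffab$direction == "homecare"),
       " home care)")

  stage("classification", {
    anchors <- unique(out$anchor_groups$anchor)
    pool <- out$anchor_groups$member
    k <- min(config$classifier_k, length(anchors))
    out$classification <- matched_subset_evaluation(
      out$table, records, pool = pool, anchors = anchors[seq_len(k)], k = k,
      n_subsets = config$classifier_subsets, seed = config$seed + 5L)
    utils::write.table(data.frame(subset = seq_along(out$classification$auc),
                                  auc = out$classification$auc),
                       file.path(config$output_dir, "classification_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note("classification: median AUC ",
       signif(out$classification$summary["median"], 3),
       " over ", length(out$classification$auc), " matched subsets")

  writeLines(c(paste0("daybiome run (config hash ", cfg_hash, ")"), log_lines),
             file.path(config$output_dir, "summary.txt"))
  writeLines(log_lines, log_path)
  invisible(out)
}
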