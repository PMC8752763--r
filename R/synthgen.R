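# Synthetic longitudinal cohort generator with planted ground truth.
#
# The generative model mirrors the statistical structure the analyses
# assume: strong subject-level compositional individuality (a per-subject
# log-abundance offset constant across a child's samples), monotone
# age-driven taxon trajectories, taxa acquired after day-care entry (some
# specific to a day-care class, some shared across all day-care children),
# a microbial maturation lag for home-care children, and multinomial read
# sampling at variable depth. Because relative abundances are a softmax of
# log-abundances, planting one feature perturbs all others (compositional
# coupling), as in real relative-abundance data.

#' Parameters for the synthetic cohort generator
#'
#' Defaults mirror the reference study design: 61 day-care children across
#' 4 facilities (B and C split into two classes), 24 home-care children
#' sampled once, day-care sampling at entry and 2, 4, 7 and 10 months after,
#' read depths lognormal with median 20k (IQR roughly 13-27k). Effect-size
#' defaults (logistic age trajectories of 1.5-2.5 natural-log units with
#' balanced directions, class taxa near 0.1-0.3% relative abundance when
#' acquired, shared day-care taxa a few-fold lighter, acquisition
#' probability 0.9 per post-entry timepoint, subject effect sd 1.2 log
#' units) are the package's chosen operating point, discussed with its
#' rationale in the methods vignette.
#'
#' @param n_daycare_children,n_homecare_children cohort sizes.
#' @param facilities named list: classes per facility.
#' @param entry_age_meanlog,entry_age_sdlog lognormal entry-age parameters
#'   (months); ages are clamped to `age_range`.
#' @param homecare_age_meanlog,homecare_age_sdlog lognormal age at the
#'   single home-care sample.
#' @param age_range allowed age range in months.
#' @param timepoint_offsets months after entry for timepoints 1..5
#'   (strictly increasing).
#' @param retention_prob probability a post-entry timepoint is sampled
#'   (timepoint 1 always is).
#' @param n_features total features.
#' @param n_age_features features with monotone logistic age trajectories.
#' @param age_effect_range trajectory amplitude range (log units).
#' @param age_midpoint_range trajectory midpoint range (months).
#' @param age_scale logistic scale (months).
#' @param prop_age_increasing fraction of age features increasing with age.
#' @param n_class_features_per_class taxa endemic to one day-care class.
#' @param n_daycare_features taxa acquired by day-care children of every
#'   class (absent in home care) — the recovery target of the matched
#'   differential-abundance analysis.
#' @param acquisition_prob_per_timepoint per post-entry timepoint switch-on
#'   probability for acquired taxa (once on, stays on).
#' @param acquired_log_mean,acquired_log_sd log-abundance of acquired
#'   class taxa when on (relative to the community log-mean of 0).
#' @param daycare_log_mean log-abundance of the shared day-care taxa when
#'   on; lighter than class taxa by default so their joint compositional
#'   footprint stays small.
#' @param subject_effect_sd per-subject, per-feature log-abundance offset sd.
#' @param sample_noise_sd per-sample log-abundance noise sd.
#' @param feature_mean_sd sd of baseline feature log-means.
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters.
#' @param maturation_lag_homecare months by which home-care age trajectories
#'   lag (home-care children are microbially "younger" at equal age).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_daycare_children = 61,
                         n_homecare_children = 24,
                         facilities = list(A = 1, B = 2, C = 2, D = 1),
                         entry_age_meanlog = log(12),
                         entry_age_sdlog = 0.5,
                         homecare_age_meanlog = log(12.6),
                         homecare_age_sdlog = 0.45,
                         age_range = c(6, 32),
                         timepoint_offsets = c(0, 2, 4, 7, 10),
                         retention_prob = 0.85,
                         n_features = 300,
                         n_age_features = 40,
                         age_effect_range = c(1.5, 2.5),
                         age_midpoint_range = c(8, 24),
                         age_scale = 3,
                         prop_age_increasing = 0.5,
                         n_class_features_per_class = 12,
                         n_daycare_features = 15,
                         acquisition_prob_per_timepoint = 0.9,
                         acquired_log_mean = 0.8,
                         acquired_log_sd = 0.5,
                         daycare_log_mean = -0.5,
                         subject_effect_sd = 1.2,
                         sample_noise_sd = 0.7,
                         feature_mean_sd = 1.5,
                         depth_meanlog = log(20000),
                         depth_sdlog = 0.54,
                         maturation_lag_homecare = 2,
                         seed = 0) {
  p <- as.list(environment())
  if (any(diff(p$timepoint_offsets) <= 0)) {
    stop_db("timepoint_offsets must be strictly increasing")
  }
  probs <- c(p$retention_prob, p$acquisition_prob_per_timepoint,
             p$prop_age_increasing)
  if (any(probs < 0 | probs > 1)) stop_db("probabilities must be in [0, 1]")
  n_classes <- sum(unlist(p$facilities))
  n_planted <- p$n_age_features + n_classes * p$n_class_features_per_class +
    p$n_daycare_features
  if (n_planted > p$n_features) {
    stop_db("more planted features (", n_planted, ") than total features (",
            p$n_features, ")")
  }
  structure(p, class = "synth_params")
}

#' Generate a synthetic longitudinal cohort
#'
#' @param params a [synth_params()] list.
#' @return a `daybiome_cohort` list: `table` (integer feature table, samples
#'   x features), `records` (metadata data.frame), `truth` (planted ground
#'   truth: `age_features`, `class_features`, `daycare_features`,
#'   `care_effect_features` — every feature whose distribution genuinely
#'   depends on care setting — plus the per-sample `acquisition` state and
#'   `subject_baseline` matrix), and `params`.
#' @export
generate_cohort <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  with_seed(p$seed, {
    classes <- unlist(lapply(names(p$facilities), function(f)
      paste0(f, seq_len(p$facilities[[f]]))))
    facility_of <- substr(classes, 1L, 1L)
    dc_ids <- sprintf("D%02d", seq_len(p$n_daycare_children))
    hc_ids <- sprintf("H%02d", seq_len(p$n_homecare_children))
    dc_class <- rep_len(classes, p$n_daycare_children)
    clamp <- function(x) pmin(pmax(x, p$age_range[1L]), p$age_range[2L])
    entry_age <- clamp(stats::rlnorm(p$n_daycare_children,
                                     p$entry_age_meanlog, p$entry_age_sdlog))
    hc_age <- clamp(stats::rlnorm(p$n_homecare_children,
                                  p$homecare_age_meanlog, p$homecare_age_sdlog))

    # --- feature roles ---------------------------------------------------
    fid <- sprintf("F%04d", seq_len(p$n_features))
    n_classes <- length(classes)
    idx_age <- seq_len(p$n_age_features)
    idx_class <- p$n_age_features +
      seq_len(n_classes * p$n_class_features_per_class)
    idx_dc <- max(c(idx_age, idx_class, 0L)) + seq_len(p$n_daycare_features)
    class_of_feature <- rep(classes, each = p$n_class_features_per_class)
    mu <- stats::rnorm(p$n_features, 0, p$feature_mean_sd)
    age_dir <- ifelse(stats::runif(p$n_age_features) < p$prop_age_increasing, 1, -1)
    age_eff <- stats::runif(p$n_age_features, p$age_effect_range[1L],
                            p$age_effect_range[2L])
    age_mid <- stats::runif(p$n_age_features, p$age_midpoint_range[1L],
                            p$age_midpoint_range[2L])
    acq_idx <- c(idx_class, idx_dc)
    acq_centers <- c(rep(p$acquired_log_mean, length(idx_class)),
                     rep(p$daycare_log_mean, length(idx_dc)))
    acq_mu <- stats::rnorm(length(acq_idx), acq_centers, p$acquired_log_sd)
    mu[acq_idx] <- acq_mu

    # --- samples ---------------------------------------------------------
    n_tp <- length(p$timepoint_offsets)
    keep_tp <- lapply(seq_len(p$n_daycare_children), function(i) {
      c(TRUE, stats::runif(n_tp - 1L) < p$retention_prob)
    })
    dc_rows <- do.call(rbind, lapply(seq_len(p$n_daycare_children), function(i) {
      tps <- which(keep_tp[[i]])
      data.frame(subject_id = dc_ids[i],
                 care_setting = "daycare",
                 facility = facility_of[match(dc_class[i], classes)],
                 class_id = dc_class[i],
                 timepoint = tps,
                 age_months = clamp(entry_age[i] + p$timepoint_offsets[tps] +
                                      stats::runif(length(tps), -0.25, 0.25)),
                 stringsAsFactors = FALSE)
    }))
    hc_rows <- data.frame(subject_id = hc_ids, care_setting = "homecare",
                          facility = NA_character_, class_id = NA_character_,
                          timepoint = NA_integer_, age_months = hc_age,
                          stringsAsFactors = FALSE)
    rec <- rbind(dc_rows, hc_rows)
    rec$sample_id <- ifelse(rec$care_setting == "daycare",
                            sprintf("%s.T%d", rec$subject_id, rec$timepoint),
                            sprintf("%s.T1", rec$subject_id))
    subjects <- c(dc_ids, hc_ids)
    per_subject <- data.frame(
      subject_id = subjects,
      sex = sample(c("male", "female"), length(subjects), replace = TRUE),
      delivery_mode = sample(c("vaginal", "cesarean"), length(subjects),
                             replace = TRUE, prob = c(0.85, 0.15)),
      breastfed_ever = stats::runif(length(subjects)) < 0.85,
      breastfeeding_current = stats::runif(length(subjects)) < 0.55,
      household_size = sample(3:6, length(subjects), replace = TRUE,
                              prob = c(0.35, 0.4, 0.15, 0.1)),
      peripartum_antibiotics = stats::runif(length(subjects)) < 0.08,
      stringsAsFactors = FALSE)
    rec <- merge(rec, per_subject, by = "subject_id", sort = FALSE)
    rec <- rec[order(rec$sample_id), , drop = FALSE]
    rownames(rec) <- NULL
    n_samp <- nrow(rec)
    subj_idx <- match(rec$subject_id, subjects)

    # --- acquisition state (class + shared day-care taxa) ----------------
    # per child x acquired feature: first post-entry timepoint at which the
    # taxon switches on (Inf = never); home care never acquires
    first_on <- matrix(Inf, length(subjects), length(acq_idx))
    is_dc_subject <- seq_along(subjects) <= p$n_daycare_children
    for (i in which(is_dc_subject)) {
      eligible <- c(rep(dc_class[i] == class_of_feature,
                        length.out = length(idx_class)),
                    rep(TRUE, length(idx_dc)))
      draws <- matrix(stats::runif(length(acq_idx) * (n_tp - 1L)) <
                        p$acquisition_prob_per_timepoint,
                      length(acq_idx), n_tp - 1L)
      fo <- apply(draws, 1L, function(d) {
        w <- which(d)
        if (length(w)) w[1L] + 1L else Inf
      })
      fo[!eligible] <- Inf
      first_on[i, ] <- fo
    }
    tp_of_sample <- ifelse(is.na(rec$timepoint), 1L, rec$timepoint)
    on <- first_on[subj_idx, , drop = FALSE] <=
      matrix(tp_of_sample, n_samp, length(acq_idx))

    # --- log-abundance assembly ------------------------------------------
    subj_base <- matrix(stats::rnorm(length(subjects) * p$n_features, 0,
                                     p$subject_effect_sd),
                        length(subjects), p$n_features,
                        dimnames = list(subjects, fid))
    eff_age <- rec$age_months -
      ifelse(rec$care_setting == "homecare", p$maturation_lag_homecare, 0)
    loga <- matrix(mu, n_samp, p$n_features, byrow = TRUE) +
      subj_base[subj_idx, , drop = FALSE] +
      matrix(stats::rnorm(n_samp * p$n_features, 0, p$sample_noise_sd),
             n_samp, p$n_features)
    if (p$n_age_features > 0L) {
      traj <- outer(eff_age, age_mid, "-") / p$age_scale
      loga[, idx_age] <- loga[, idx_age] +
        stats::plogis(traj) %*% diag(age_dir * age_eff, p$n_age_features) -
        matrix(age_dir * age_eff / 2, n_samp, p$n_age_features, byrow = TRUE)
    }
    loga[, acq_idx][!on] <- -Inf

    # --- multinomial read sampling ---------------------------------------
    depth <- pmax(1000L, as.integer(round(stats::rlnorm(n_samp, p$depth_meanlog,
                                                        p$depth_sdlog))))
    w <- exp(loga)
    counts <- t(vapply(seq_len(n_samp), function(s) {
      pr <- w[s, ] / sum(w[s, ])
      drop(stats::rmultinom(1L, depth[s], pr))
    }, integer(p$n_features)))
    dimnames(counts) <- list(rec$sample_id, fid)

    truth <- list(
      age_features = data.frame(feature_id = fid[idx_age],
                                direction = ifelse(age_dir > 0, "up", "down"),
                                effect = age_eff, midpoint = age_mid,
                                stringsAsFactors = FALSE),
      class_features = split(fid[idx_class], class_of_feature),
      daycare_features = fid[idx_dc],
      care_effect_features = unique(c(
        fid[idx_class], fid[idx_dc],
        if (p$maturation_lag_homecare != 0) fid[idx_age])),
      acquisition = structure(on, dimnames = list(rec$sample_id,
                                                  fid[acq_idx])),
      subject_baseline = subj_base)

    cols <- c("sample_id", "subject_id", "age_months", "care_setting",
              "facility", "class_id", "timepoint", "sex", "delivery_mode",
              "breastfed_ever", "breastfeeding_current", "household_size",
              "peripartum_antibiotics")
    structure(list(table = counts, records = rec[, cols], truth = truth,
                   params = p),
              class = "daybiome_cohort")
  })
}

#' @export
print.daybiome_cohort <- function(x, ...) {
  cat("Synthetic day-care cohort:", nrow(x$table), "samples,",
      ncol(x$table), "features\n")
  cat("  daycare children:", x$params$n_daycare_children,
      "| homecare children:", x$params$n_homecare_children, "\n")
  cat("  planted: ", nrow(x$truth$age_features), " age features, ",
      length(unlist(x$truth$class_features)), " class features, ",
      length(x$truth$daycare_features), " shared day-care features\n", sep = "")
  invisible(x)
}

#' Write a cohort bundle as plain-text fixtures
#'
#' Writes `feature_table.tsv` (samples as rows), `metadata.tsv`,
#' `ground_truth.tsv` and `params.yaml` into `directory`; the tables
#' round-trip through [read_feature_table()] / [read_metadata()].
#'
#' @param bundle a `daybiome_cohort`.
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(bundle, directory, overwrite = FALSE) {
  if (dir.exists(directory) && length(dir(directory)) && !overwrite) {
    stop_db("directory '", directory, "' is not empty; use overwrite = TRUE")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(sample_id = rownames(bundle$table),
                                bundle$table, check.names = FALSE),
                     file.path(directory, "feature_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$records, file.path(directory, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  gt <- ground_truth_frame(bundle$truth)
  utils::write.table(gt, file.path(directory, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  writeLines(yaml::as.yaml(unclass(bundle$params)[
    !vapply(unclass(bundle$params), is.list, logical(1L))]),
    file.path(directory, "params.yaml"))
  invisible(directory)
}

ground_truth_frame <- function(truth) {
  rows <- list(
    data.frame(feature_id = truth$age_features$feature_id, role = "age",
               class_id = NA_character_,
               direction = truth$age_features$direction,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(truth$class_features), function(cl) {
      if (!length(truth$class_features[[cl]])) return(NULL)
      data.frame(feature_id = truth$class_features[[cl]], role = "class",
                 class_id = cl, direction = NA_character_,
                 stringsAsFactors = FALSE)
    })),
    if (length(truth$daycare_features)) {
      data.frame(feature_id = truth$daycare_features, role = "daycare",
                 class_id = NA_character_, direction = NA_character_,
                 stringsAsFactors = FALSE)
    })
  do.call(rbind, rows)
}
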