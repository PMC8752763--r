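# Sequential PERMANOVA variance partitioning on distance matrices, with
# optional subject strata for longitudinal designs. The fitting engine is
# vegan::adonis2 (terms added sequentially, first to last); this module owns
# term assembly, missing-data handling and the tidy result layout.

#' Sequential PERMANOVA on a distance matrix
#'
#' Partitions the (Gower-centered) distance-matrix variance over `terms`
#' added in the given order (Type-I); per-term R2 is SS_term / SS_total.
#' When `strata` names a metadata column, permutations are restricted within
#' its blocks (e.g. within subject, the longitudinal control for repeated
#' sampling); singleton blocks are simply fixed under permutation. Samples
#' with missing values in any used term are dropped and logged.
#'
#' @param dm symmetric distance matrix with sample-id dimnames.
#' @param records metadata data.frame.
#' @param terms character vector of metadata column names, in the order they
#'   enter the model (order matters with correlated covariates and is
#'   logged).
#' @param strata optional metadata column name defining permutation blocks.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   columns `term`, `df`, `SS`, `R2`, `pseudo_F`, `p_value`.
#' @export
permanova <- function(dm, records, terms, strata = NULL, n_perm = 999, seed = 0) {
  ids <- intersect(rownames(dm), records$sample_id)
  rec <- records[match(ids, records$sample_id), , drop = FALSE]
  used <- c(terms, strata)
  miss <- setdiff(used, names(rec))
  if (length(miss)) stop_db("unknown metadata term(s): ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(rec[, used, drop = FALSE])
  if (any(!ok)) {
    db_log("permanova: dropping ", sum(!ok),
           " sample(s) with missing values in terms: ",
           paste(rec$sample_id[!ok], collapse = ", "))
  }
  rec <- rec[ok, , drop = FALSE]
  d <- stats::as.dist(dm[rec$sample_id, rec$sample_id])
  for (tm in terms) {
    v <- rec[[tm]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop_db("term '", tm, "' has a single level after filtering")
    }
  }
  db_log("permanova: terms entered sequentially: ", paste(terms, collapse = " + "))
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  fit <- with_seed(seed, vegan::adonis2(
    fml, data = rec, permutations = n_perm, by = "terms",
    strata = if (!is.null(strata)) as.factor(rec[[strata]]) else NULL))
  out <- data.frame(term = rownames(fit),
                    df = fit$Df,
                    SS = fit$SumOfSqs,
                    R2 = fit$R2,
                    pseudo_F = fit$F,
                    p_value = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-variable variance partition controlling age and sex
#'
#' For each focal variable, fits a sequential PERMANOVA with the covariates
#' first (dropping a covariate when it is itself the focal variable) and
#' reports the focal variable's row — the "variance explained after age and
#' sex" summary used for longitudinal cohorts. With `strata = "subject_id"`
#' permutations respect repeated sampling; to quantify the subject effect
#' itself, pass `"subject_id"` as a focal term (it is then fitted as a term,
#' without strata).
#'
#' @param dm distance matrix.
#' @param records metadata data.frame.
#' @param focal_terms character vector of variables to quantify.
#' @param covariates variables controlled first (default
#'   `c("age_months", "sex")`).
#' @param strata optional blocking column (ignored for the focal term equal
#'   to it).
#' @param n_perm permutations per fit.
#' @param seed integer seed.
#' @return data.frame, one row per focal term: `term`, `df`, `R2`,
#'   `pseudo_F`, `p_value`.
#' @export
variance_partition <- function(dm, records, focal_terms,
                               covariates = c("age_months", "sex"),
                               strata = NULL, n_perm = 999, seed = 0) {
  rows <- lapply(focal_terms, function(tm) {
    covs <- setdiff(covariates, tm)
    st <- if (!is.null(strata) && identical(tm, strata)) NULL else strata
    fit <- permanova(dm, records, terms = c(covs, tm), strata = st,
                     n_perm = n_perm, seed = seed)
    fit[fit$term == tm, c("term", "df", "R2", "pseudo_F", "p_value")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a PERMANOVA table as TSV
#'
#' @param result data.frame from [permanova()] or [variance_partition()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_permanova <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
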