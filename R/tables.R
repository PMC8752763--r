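# Feature-table and metadata I/O, rarefaction, alpha diversity and age-bin
# aggregation.
#
# A feature table is an integer matrix with samples as rows and ASV features
# as columns; sample ids are rownames and feature ids colnames. Metadata is a
# data.frame of per-sample covariates validated against the column dictionary
# shipped in inst/extdata/metadata_dictionary.tsv.

#' Read a tab-separated ASV feature table
#'
#' @param path path to a TSV file with one header row of ids and one id
#'   column first.
#' @param orientation `"samples_rows"` if rows are samples (the package's
#'   internal convention) or `"samples_cols"` if the file stores samples as
#'   columns (the common BIOM-style export); the table is transposed on read.
#' @return an integer matrix, samples x features, with unique dimnames.
#' @export
read_feature_table <- function(path, orientation = c("samples_rows", "samples_cols")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop_db("no samples: table at '", path, "' has no data rows/columns")
  }
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "samples_cols") mat <- t(mat)
  validate_feature_table(mat)
  storage.mode(mat) <- "integer"
  mat
}

validate_feature_table <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_db("feature table must have sample and feature ids as dimnames")
  }
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup)) stop_db("duplicate sample id: ", dup[1L])
  dup <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup)) stop_db("duplicate feature id: ", dup[1L])
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_db("invalid count at sample '", rownames(mat)[bad[1L, 1L]],
            "', feature '", colnames(mat)[bad[1L, 2L]],
            "': counts must be non-negative integers")
  }
  if (nrow(mat) == 0L) stop_db("no samples")
  invisible(mat)
}

#' Read a sample-metadata table
#'
#' Columns follow the dictionary in
#' `system.file("extdata", "metadata_dictionary.tsv", package = "daybiome")`.
#' Required: `sample_id`, `subject_id`, `age_months`, `care_setting`.
#' Day-care samples must carry `facility`, `class_id` and `timepoint` (1-5);
#' home-care samples must leave them empty. Unknown columns are carried
#' through untouched so they remain available as PERMANOVA terms.
#'
#' @param path path to a TSV file with a header; missing values are empty
#'   strings.
#' @return a validated data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  validate_metadata(coerce_metadata(raw))
}

coerce_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "age_months", "care_setting")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_db("metadata missing required column(s): ",
                            paste(miss, collapse = ", "))
  blank_to_na <- function(x) { x[trimws(x) == ""] <- NA; x }
  df[] <- lapply(df, function(col) if (is.character(col)) blank_to_na(col) else col)
  df$age_months <- as.numeric(df$age_months)
  if ("timepoint" %in% names(df)) df$timepoint <- as.integer(df$timepoint)
  if ("household_size" %in% names(df)) df$household_size <- as.integer(df$household_size)
  for (col in c("breastfed_ever", "breastfeeding_current", "peripartum_antibiotics")) {
    if (col %in% names(df)) df[[col]] <- parse_logical(df[[col]])
  }
  df
}

validate_metadata <- function(df) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop_db("duplicate sample_id: ", dup[1L])
  if (anyNA(df$age_months) || any(df$age_months <= 0)) {
    stop_db("age_months must be present and > 0 for every sample")
  }
  if (!all(df$care_setting %in% c("daycare", "homecare"))) {
    stop_db("care_setting must be 'daycare' or 'homecare'")
  }
  dc <- df$care_setting == "daycare"
  if (any(dc)) {
    for (col in c("facility", "class_id", "timepoint")) {
      if (!col %in% names(df) || anyNA(df[[col]][dc])) {
        stop_db("daycare sample '", df$sample_id[dc & (if (col %in% names(df))
          is.na(df[[col]]) else TRUE)][1L], "' lacks required field '", col, "'")
      }
    }
    tp <- df$timepoint[dc]
    if (any(tp < 1L | tp > 5L)) {
      stop_db("daycare timepoint out of range 1-5 for sample '",
              df$sample_id[dc][which(tp < 1L | tp > 5L)[1L]], "'")
    }
    key <- paste(df$subject_id[dc], df$timepoint[dc])
    if (anyDuplicated(key)) {
      stop_db("duplicate (subject_id, timepoint) among daycare samples: ",
              key[duplicated(key)][1L])
    }
  }
  hc <- df$care_setting == "homecare"
  for (col in c("facility", "class_id", "timepoint")) {
    if (col %in% names(df) && any(hc) && any(!is.na(df[[col]][hc]))) {
      stop_db("homecare sample '", df$sample_id[hc & !is.na(df[[col]])][1L],
              "' must not carry '", col, "'")
    }
  }
  df
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`;
#' samples with fewer total reads are dropped (and logged), never upsampled.
#' The default depth of 4000 reads is the conventional depth for alpha- and
#' beta-diversity analysis in this design.
#'
#' @param table integer matrix, samples x features.
#' @param depth target read depth per sample.
#' @param seed integer; the subsampling is deterministic given
#'   `(table, depth, seed)`.
#' @return an integer matrix of the retained samples with every row summing
#'   to `depth`; attributes `depth` and `seed` record the call.
#' @export
rarefy <- function(table, depth = 4000, seed = 0) {
  if (depth < 1) stop_db("depth must be >= 1")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop_db("no samples at depth ", depth)
  if (any(!keep)) {
    db_log("rarefy: dropping ", sum(!keep), " sample(s) below depth ", depth,
           ": ", paste(rownames(table)[!keep], collapse = ", "))
  }
  kept <- table[keep, , drop = FALSE]
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(kept, depth),
    # vegan flags tables whose smallest positive count exceeds 1 as
    # "probably not counts"; validated integer input makes this spurious
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(out) <- "integer"
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Observed features (alpha diversity)
#'
#' Number of features with non-zero count per sample. Meaningful on a
#' rarefied table (documented requirement, not enforced).
#'
#' @param table matrix, samples x features.
#' @return named integer vector, one value per sample.
#' @export
observed_features <- function(table) {
  out <- as.integer(rowSums(table > 0))
  names(out) <- rownames(table)
  out
}

#' Bin alpha diversity by age with within-bin subject joining
#'
#' Samples are stratified into age bins of `bin_width_months`. When a bin
#' contains several samples of one subject they are first joined at the
#' relative-frequency level — relative abundances are averaged across the
#' subject's samples in the bin and the joined observed-feature count is the
#' number of features with positive mean frequency (the union of the presence
#' sets) — so each subject contributes at most one alpha value per bin.
#'
#' @param table rarefied feature table (samples x features).
#' @param records metadata data.frame aligned by `sample_id`.
#' @param bin_width_months bin width in months (default 5).
#' @return data.frame with columns `bin` (left edge, months), `care_setting`,
#'   `subject_id`, `alpha`.
#' @export
bin_alpha_by_age <- function(table, records, bin_width_months = 5) {
  records <- records[match(rownames(table), records$sample_id), , drop = FALSE]
  if (anyNA(records$sample_id)) {
    stop_db("every table sample must appear in the metadata")
  }
  freq <- table / pmax(rowSums(table), 1L)
  bin <- floor(records$age_months / bin_width_months) * bin_width_months
  key <- interaction(records$subject_id, bin, drop = TRUE)
  rows <- split(seq_len(nrow(table)), key)
  out <- lapply(rows, function(idx) {
    joined <- colMeans(freq[idx, , drop = FALSE])
    data.frame(bin = bin[idx[1L]],
               care_setting = records$care_setting[idx[1L]],
               subject_id = records$subject_id[idx[1L]],
               alpha = sum(joined > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$bin, out$care_setting, out$subject_id), , drop = FALSE]
}

#' Per-bin two-group comparison of binned alpha diversity
#'
#' Runs a two-sided Mann-Whitney test between care settings within every age
#' bin holding both groups; bins with a missing group are omitted with a log
#' message.
#'
#' @param binned output of [bin_alpha_by_age()].
#' @return data.frame with columns `bin`, `n_daycare`, `n_homecare`,
#'   `median_daycare`, `median_homecare`, `p_value`.
#' @export
compare_alpha_bins <- function(binned) {
  res <- lapply(split(binned, binned$bin), function(b) {
    x <- b$alpha[b$care_setting == "daycare"]
    y <- b$alpha[b$care_setting == "homecare"]
    if (!length(x) || !length(y)) {
      db_log("alpha bin ", b$bin[1L], " lacks one care setting; omitted")
      return(NULL)
    }
    tst <- mann_whitney(x, y, alternative = "two_sided")
    data.frame(bin = b$bin[1L], n_daycare = length(x), n_homecare = length(y),
               median_daycare = stats::median(x), median_homecare = stats::median(y),
               p_value = tst$p_value)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop_db("no age bin contains both care settings")
  rownames(out) <- NULL
  out
}
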