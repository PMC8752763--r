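# Shared fixtures and independent oracles, all built in code.

# small random count table, samples x features
random_table <- function(n_samples, n_features, seed, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_features, lambda), n_samples, n_features,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("f", seq_len(n_features))))
  m
}

# minimal valid metadata frame
make_records <- function(sample_id, subject_id, age_months, care_setting,
                         facility = NA, class_id = NA, timepoint = NA,
                         sex = "female") {
  data.frame(sample_id = sample_id, subject_id = subject_id,
             age_months = age_months, care_setting = care_setting,
             facility = facility, class_id = class_id, timepoint = timepoint,
             sex = sex, stringsAsFactors = FALSE)
}

# set-arithmetic brute force for binary Jaccard (independent of the
# matrix-algebra implementation)
jaccard_bruteforce <- function(table) {
  pres <- apply(table > 0, 1L, function(r) colnames(table)[r],
                simplify = FALSE)
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- union(pres[[i]], pres[[j]])
    d[i, j] <- if (length(u)) 1 - length(intersect(pres[[i]], pres[[j]])) / length(u) else 0
  }
  d
}

# star tree over the given tip labels, unit branch lengths
star_tree <- function(tips) {
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# direct sequential (Type-I) distance-matrix partitioning: Gower-centered
# -D^2/2, hat-matrix projections of nested model matrices
permanova_oracle <- function(dm, df, terms) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * ctr %*% d2 %*% ctr
  ss_total <- sum(diag(g))
  ss <- numeric(length(terms))
  prev_hat <- matrix(1 / n, n, n)  # intercept projection
  for (k in seq_along(terms)) {
    x <- stats::model.matrix(stats::as.formula(
      paste("~", paste(terms[seq_len(k)], collapse = "+"))), df)
    hat <- x %*% solve(crossprod(x), t(x))
    ss[k] <- sum(diag(hat %*% g %*% hat)) - sum(diag(prev_hat %*% g %*% prev_hat))
    prev_hat <- hat
  }
  list(R2 = ss / ss_total, SS = ss, ss_total = ss_total)
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# scaled-down cohort for smoke tests
small_params <- function(seed = 0, ...) {
  synth_params(n_daycare_children = 24, n_homecare_children = 10,
               n_features = 120, n_age_features = 16,
               n_class_features_per_class = 6, n_daycare_features = 8,
               seed = seed, ...)
}
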