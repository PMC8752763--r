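# Pairwise dissimilarities and principal coordinates analysis.
#
# Distance matrices are full symmetric numeric matrices with sample ids as
# dimnames (interoperable with TSV writers below and convertible to 'dist'
# for vegan).

#' Binary Jaccard distance
#'
#' For presence sets \eqn{B_i, B_j} (features with count > 0),
#' \deqn{D_{ij} = 1 - |B_i \cap B_j| / |B_i \cup B_j|.}
#' Presence/absence only, so the distance is invariant to count magnitude.
#' A pair of all-zero samples gets distance 0 by convention (logged), so
#' downstream tests never see missing values.
#'
#' @param table matrix, samples x features (counts; typically rarefied).
#' @return symmetric distance matrix with zero diagonal, values in \[0, 1\].
#' @export
binary_jaccard <- function(table) {
  if (nrow(table) < 2L) stop_db("need >= 2 samples")
  p <- (table > 0) * 1
  inter <- tcrossprod(p)
  sizes <- rowSums(p)
  union <- outer(sizes, sizes, "+") - inter
  if (any(sizes == 0)) {
    db_log("binary_jaccard: ", sum(sizes == 0),
           " all-zero sample(s); their mutual distances set to 0 by convention")
  }
  d <- ifelse(union > 0, 1 - inter / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{1 - 2\sum_k \min(x_k, y_k) / \sum_k (x_k + y_k)}; intended for
#' rarefied (equal-depth) tables.
#'
#' @inheritParams binary_jaccard
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2L) stop_db("need >= 2 samples")
  zero <- rowSums(table) == 0
  if (any(zero)) {
    db_log("bray_curtis: ", sum(zero),
           " all-zero sample(s); pairwise values involving them set to 0")
  }
  d <- as.matrix(vegan::vegdist(table, method = "bray"))
  d[zero, ] <- 0
  d[, zero] <- 0
  diag(d) <- 0
  d
}

#' Unweighted UniFrac distance
#'
#' Classical unweighted UniFrac: per pair, the branch length leading only to
#' tips present in exactly one of the two samples, divided by the branch
#' length leading to tips present in either. Branches whose descendants are
#' absent from both samples contribute to neither sum.
#'
#' @param table matrix, samples x features; every feature with non-zero
#'   count must be a tip of `tree`.
#' @param tree a rooted `phylo` tree with branch lengths; tip labels are
#'   feature ids.
#' @return symmetric distance matrix with values in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  if (!inherits(tree, "phylo")) stop_db("'tree' must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop_db("tree must have branch lengths")
  used <- colnames(table)[colSums(table) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) {
    stop_db("feature(s) missing from tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  pres_tip <- matrix(FALSE, nrow(table), ntip)
  hit <- match(colnames(table), tree$tip.label)
  ok <- !is.na(hit)
  pres_tip[, hit[ok]] <- table[, ok, drop = FALSE] > 0
  # presence below every node, accumulated child -> parent in postorder
  pres <- matrix(FALSE, nrow(table), ntip + nnode)
  pres[, seq_len(ntip)] <- pres_tip
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    pres[, parent] <- pres[, parent] | pres[, child]
  }
  # one column per edge: presence of the edge's child clade
  pe <- pres[, tree$edge[, 2L], drop = FALSE]
  len <- tree$edge.length
  shared <- (pe * rep(len, each = nrow(pe))) %*% t(pe)  # sum len over both-present
  covered <- pe %*% len                                  # per-sample branch length
  either <- outer(drop(covered), drop(covered), "+") - shared
  uniq <- either - shared
  d <- ifelse(either > 0, uniq / either, 0)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-D^2/2}, eigendecomposes, and scales eigenvectors by
#' the square roots of positive eigenvalues. Negative eigenvalues (from
#' non-Euclidean distances such as Jaccard) are kept in the record, but
#' `proportion_explained` is computed over the sum of positive eigenvalues
#' only, the usual ecology convention, so PC1's share is well defined.
#'
#' @param dm symmetric distance matrix with sample-id dimnames.
#' @return object of class `daybiome_pcoa`: list with `sample_ids`,
#'   `coordinates` (samples x positive axes), `eigenvalues` (all, decreasing)
#'   and `proportion_explained` (per positive axis).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop_db("pcoa needs at least 3 samples")
  a <- -0.5 * dm^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12 & eg$values > 0
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                     nrow = sum(pos))
  # eigenvector signs are arbitrary; orient each axis so its largest-
  # magnitude coordinate is positive, making ordinations reproducible
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(sample_ids = rownames(dm),
                 coordinates = coords,
                 eigenvalues = eg$values,
                 proportion_explained = eg$values[pos] / sum(eg$values[pos])),
            class = "daybiome_pcoa")
}

#' @export
print.daybiome_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "positive axes\n")
  pe <- round(100 * x$proportion_explained[seq_len(min(3, ncol(x$coordinates)))], 1)
  cat("  proportion explained (first axes): ", paste0(pe, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a distance matrix as square TSV
#'
#' Plain square TSV with an id header row and id first column, the layout
#' common ecology tools exchange.
#'
#' @param dm symmetric distance matrix.
#' @param path file path.
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop_db("distance matrix at '", path, "' is not symmetric")
  }
  m
}

# Extract the lower-triangle distances for a set of unordered pairs.
pair_distances <- function(dm, a, b) {
  dm[cbind(match(a, rownames(dm)), match(b, rownames(dm)))]
}
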