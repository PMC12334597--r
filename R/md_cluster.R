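#' Relative microbial abundance
#'
#' Scales every sample column of a microbial count table to sum to 1. Feature
#' and sample order are preserved; the operation is idempotent and invariant
#' to per-sample rescaling of the counts.
#'
#' @param microbes A \code{feature_table} of kind \code{"microbe"}.
#' @return A \code{feature_table} of per-sample proportions.
#' @export
relative_abundance <- function(microbes) {
  validate_feature_table(microbes)
  tot <- colSums(microbes$counts)
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero total microbial count: ",
         paste(zero, collapse = ", "))
  out <- microbes
  out$counts <- sweep(microbes$counts, 2, tot, "/")
  out
}

# Spearman correlation matrix between the columns of `m`, after dropping rows
# constant across all columns (correlation undefined there). Errors if any
# column is constant over the retained rows.
spearman_cor_cols <- function(m, what = "sample") {
  keep <- apply(m, 1, function(r) length(unique(r)) > 1L)
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped before correlation")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need at least 3 non-constant features")
  const <- apply(m, 2, function(x) length(unique(x)) == 1L)
  if (any(const))
    stop("constant ", what, " profile(s): ",
         paste(colnames(m)[const], collapse = ", "))
  stats::cor(m, method = "spearman")
}

# Relabel cluster ids 1..k by decreasing size; ties broken by the smallest
# member ID (lexicographic).
relabel_by_size <- function(labels) {
  ids <- names(labels)
  info <- lapply(sort(unique(labels)), function(l)
    list(old = l, size = sum(labels == l), first = min(ids[labels == l])))
  ord <- order(-vapply(info, `[[`, 0, "size"),
               vapply(info, `[[`, "", "first"))
  map <- integer(length(info))
  map[vapply(info, `[[`, 0L, "old")[ord]] <- seq_along(info)
  stats::setNames(map[labels], ids)
}

#' Microbe-derived sample clustering (MD-Clusters)
#'
#' Clusters samples by their microbial profiles: pairwise sample distance is
#' 1 - Spearman rho across features, agglomerated with average linkage, and
#' the tree is cut into exactly \code{k} clusters. Labels 1..k are assigned by
#' decreasing cluster size (ties broken by the lexicographically smallest
#' member sample ID), so label 1 is always the largest cluster. The full merge
#' history is retained for inspection of sub-cluster structure.
#'
#' @param abundance A \code{feature_table}, typically relative abundance from
#'   \code{\link{relative_abundance}}. Features constant across all samples
#'   are dropped with a warning.
#' @param k Number of clusters, default 2.
#' @return An object of class \code{"sample_clustering"}: list with
#'   \code{sample_ids}, \code{labels} (named integer vector), \code{k}, and
#'   \code{hclust} (the merge history).
#' @export
cluster_samples <- function(abundance, k = 2) {
  validate_feature_table(abundance)
  n <- ncol(abundance$counts)
  if (k > n) stop("k exceeds the number of samples")
  rho <- spearman_cor_cols(abundance$counts, "sample")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  labels <- relabel_by_size(stats::cutree(hc, k = k))
  structure(list(sample_ids = colnames(abundance$counts),
                 labels = labels[colnames(abundance$counts)], k = k,
                 hclust = hc),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample_clustering: %d samples in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Test association between MD-Cluster and patient group
#'
#' Builds the 2x2 cluster-by-group contingency table (samples with missing
#' group are dropped) and applies Fisher's exact test, the test used to
#' report the race-related separation of the two MD-Clusters.
#'
#' @param clustering A \code{sample_clustering} with k = 2.
#' @param ann Sample annotation data frame with \code{sample_id} and
#'   \code{group} columns; exactly two group levels must be present.
#' @return An \code{mh_contingency} result carrying the table and p-value.
#' @export
associate_clusters_with_group <- function(clustering, ann) {
  stopifnot(inherits(clustering, "sample_clustering"))
  ann <- ann[!is.na(ann$group) & ann$sample_id %in% names(clustering$labels), ]
  labels <- clustering$labels[ann$sample_id]
  tab <- table(cluster = labels, group = ann$group)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need 2 clusters and 2 groups among annotated samples")
  if (nrow(tab) != 2L || ncol(tab) != 2L)
    stop("association test requires a 2x2 cluster-by-group table")
  res <- fisher_exact(unclass(tab))
  res$table <- tab
  res
}
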