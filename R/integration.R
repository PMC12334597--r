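#' Combine host and microbial feature tables into a single matrix
#'
#' Row-binds the two tables after aligning the microbial samples to the host
#' table's sample order. Sample ID sets must be identical (order may differ)
#' and feature IDs must be disjoint; kind tags are preserved.
#'
#' @param host A \code{feature_table} of kind \code{"host_gene"}.
#' @param microbes A \code{feature_table} of kind \code{"microbe"}.
#' @return A combined \code{feature_table}.
#' @export
combine_tables <- function(host, microbes) {
  validate_feature_table(host)
  validate_feature_table(microbes)
  sh <- sample_ids(host); sm <- sample_ids(microbes)
  extra <- c(setdiff(sh, sm), setdiff(sm, sh))
  if (length(extra))
    stop("sample ID mismatch between tables: ", paste(extra, collapse = ", "))
  clash <- intersect(feature_ids(host), feature_ids(microbes))
  if (length(clash))
    stop("feature ID collision: ", paste(clash, collapse = ", "))
  counts <- rbind(host$counts, microbes$counts[, sh, drop = FALSE])
  feature_table(counts, c(host$kind, microbes$kind))
}

#' Hierarchically cluster features by co-abundance
#'
#' Clusters the rows (features) of a combined host + microbe table: pairwise
#' feature distance is 1 - Spearman rho across samples, agglomerated with
#' average linkage, and the tree is cut into exactly \code{K} clusters.
#' Values are expected to be log2(x + 1) transformed (see
#' \code{\link{log2_transform}}); because Spearman correlation is invariant
#' to monotone transforms this affects only the stored values, not the tree.
#' Features constant across all samples are dropped with a warning and listed
#' in the \code{dropped} element.
#'
#' @param combined A \code{feature_table} (host genes + microbes).
#' @param K Number of clusters; must not exceed the number of retained
#'   (non-constant) features.
#' @return An object of class \code{"feature_clustering"}: list with
#'   \code{assignment} (named integer vector, feature -> cluster id),
#'   \code{kind} (tags of retained features), \code{K}, \code{hclust},
#'   \code{dropped}.
#' @export
cluster_features <- function(combined, K) {
  validate_feature_table(combined)
  m <- combined$counts
  const <- apply(m, 1, function(r) length(unique(r)) == 1L)
  dropped <- rownames(m)[const]
  if (length(dropped)) {
    warning(length(dropped), " constant feature(s) dropped before clustering")
    m <- m[!const, , drop = FALSE]
  }
  if (K > nrow(m))
    stop("K (", K, ") exceeds the number of retained features (", nrow(m), ")")
  rho <- stats::cor(t(m), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  assignment <- stats::cutree(hc, k = K)
  structure(list(assignment = assignment,
                 kind = combined$kind[rownames(m)],
                 K = K, hclust = hc, dropped = dropped),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("feature_clustering: %d features in %d clusters (%d dropped as constant)\n",
              length(x$assignment), x$K, length(x$dropped)))
  invisible(x)
}

#' Classify feature clusters as homologous or heterologous
#'
#' A cluster containing only host genes is \code{host_only}, only microbes is
#' \code{microbe_only} (these two are the homologous classes), and a cluster
#' with at least one of each kind is \code{heterologous}. The three class
#' counts always partition K.
#'
#' @param clustering A \code{feature_clustering}, or a named integer
#'   assignment vector (then \code{kind} must be supplied).
#' @param kind Optional named kind vector when \code{clustering} is a bare
#'   assignment.
#' @return A data frame of class \code{"hetero_clusters"}, one row per
#'   cluster: \code{cluster_id}, \code{n_host}, \code{n_microbe},
#'   \code{classification}, plus placeholder columns \code{best_gene},
#'   \code{best_microbe}, \code{best_rho}, \code{presence_ok},
#'   \code{high_confidence} filled by \code{\link{call_high_confidence}}.
#'   The assignment is attached as attribute \code{"assignment"}.
#' @export
classify_clusters <- function(clustering, kind = NULL) {
  if (inherits(clustering, "feature_clustering")) {
    assignment <- clustering$assignment
    kind <- clustering$kind
  } else {
    assignment <- clustering
    if (is.null(kind)) stop("`kind` required with a bare assignment vector")
    kind <- kind[names(assignment)]
  }
  ids <- sort(unique(assignment))
  n_host <- vapply(ids, function(k)
    sum(kind[assignment == k] == "host_gene"), 0L)
  n_microbe <- vapply(ids, function(k)
    sum(kind[assignment == k] == "microbe"), 0L)
  classification <- ifelse(n_host > 0 & n_microbe > 0, "heterologous",
                           ifelse(n_host > 0, "host_only", "microbe_only"))
  out <- data.frame(cluster_id = ids, n_host = n_host, n_microbe = n_microbe,
                    classification = classification,
                    best_gene = NA_character_, best_microbe = NA_character_,
                    best_rho = NA_real_, presence_ok = NA,
                    high_confidence = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "assignment") <- assignment
  attr(out, "kind") <- kind
  class(out) <- c("hetero_clusters", "data.frame")
  out
}

#' @export
print.hetero_clusters <- function(x, ...) {
  cl <- table(factor(x$classification,
                     levels = c("host_only", "microbe_only", "heterologous")))
  cat(sprintf("hetero_clusters: %d clusters (%d host_only, %d microbe_only, %d heterologous)",
              nrow(x), cl[["host_only"]], cl[["microbe_only"]],
              cl[["heterologous"]]))
  if (any(!is.na(x$best_rho)))
    cat(sprintf(", %d high-confidence", sum(x$high_confidence)))
  cat("\n")
  invisible(x)
}

#' Call high-confidence heterologous clusters
#'
#' For every heterologous cluster, evaluates each cross-kind (gene, microbe)
#' member pair whose both members are non-zero in at least \code{min_presence}
#' of samples, computes the Spearman correlation across samples for each
#' eligible pair, and records the best pair (ties broken by the
#' lexicographically smallest gene then microbe ID). A cluster is
#' high-confidence when its best eligible pair exceeds \code{rho_min}.
#' Clusters with no eligible pair get \code{presence_ok = FALSE} and are never
#' high-confidence. All eligible pairs are retained in the \code{"pairs"}
#' attribute (columns \code{cluster_id}, \code{gene}, \code{microbe},
#' \code{rho}, \code{high_confidence}).
#'
#' Presence is evaluated on the count scale (a cell is present iff its value
#' is non-zero, which the log2(x + 1) transform preserves).
#'
#' @param records A \code{hetero_clusters} object from
#'   \code{\link{classify_clusters}}.
#' @param combined The combined \code{feature_table} the clustering was run
#'   on.
#' @param rho_min Spearman correlation cutoff, default 0.7.
#' @param min_presence Minimum fraction of samples in which both pair members
#'   must be non-zero, default 0.5.
#' @return The \code{records} data frame with \code{best_gene},
#'   \code{best_microbe}, \code{best_rho}, \code{presence_ok} and
#'   \code{high_confidence} filled for heterologous clusters.
#' @export
call_high_confidence <- function(records, combined, rho_min = 0.7,
                                 min_presence = 0.5) {
  stopifnot(inherits(records, "hetero_clusters"))
  validate_feature_table(combined)
  assignment <- attr(records, "assignment")
  kind <- attr(records, "kind")
  m <- combined$counts
  n <- ncol(m)
  present <- rowMeans(m != 0) >= min_presence
  pairs <- list()
  for (i in which(records$classification == "heterologous")) {
    cid <- records$cluster_id[i]
    members <- names(assignment)[assignment == cid]
    genes <- sort(members[kind[members] == "host_gene"])
    microbes <- sort(members[kind[members] == "microbe"])
    genes_ok <- genes[present[genes]]
    microbes_ok <- microbes[present[microbes]]
    if (length(genes_ok) == 0L || length(microbes_ok) == 0L) {
      records$presence_ok[i] <- FALSE
      next
    }
    records$presence_ok[i] <- TRUE
    grid <- expand.grid(gene = genes_ok, microbe = microbes_ok,
                        stringsAsFactors = FALSE)
    grid$rho <- vapply(seq_len(nrow(grid)), function(j)
      stats::cor(m[grid$gene[j], ], m[grid$microbe[j], ],
                 method = "spearman"), 0)
    grid <- grid[order(-grid$rho, grid$gene, grid$microbe), ]
    records$best_gene[i] <- grid$gene[1]
    records$best_microbe[i] <- grid$microbe[1]
    records$best_rho[i] <- grid$rho[1]
    records$high_confidence[i] <- grid$rho[1] > rho_min
    grid$cluster_id <- cid
    grid$high_confidence <- grid$rho > rho_min
    pairs[[length(pairs) + 1L]] <- grid
  }
  pair_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene = character(), microbe = character(), rho = numeric(),
               cluster_id = integer(), high_confidence = logical())
  attr(records, "pairs") <-
    pair_df[, c("cluster_id", "gene", "microbe", "rho", "high_confidence")]
  records
}

#' Run the full host-microbe integration
#'
#' Convenience wrapper chaining \code{\link{combine_tables}},
#' \code{\link{log2_transform}}, \code{\link{cluster_features}},
#' \code{\link{classify_clusters}} and \code{\link{call_high_confidence}}.
#' K defaults to min(1000, floor(n_features / 2)) so small cohorts do not
#' violate the K <= features precondition; a dataset with thousands of
#' features uses the standard K = 1000.
#'
#' @param host,microbes Raw count \code{feature_table}s sharing samples.
#' @param K Number of feature clusters; see default above.
#' @param rho_min,min_presence Passed to \code{\link{call_high_confidence}}.
#' @return A \code{hetero_clusters} object with attributes \code{"pairs"}
#'   and \code{"clustering"}.
#' @export
integrate_features <- function(host, microbes, K = NULL, rho_min = 0.7,
                               min_presence = 0.5) {
  combined <- log2_transform(combine_tables(host, microbes))
  if (is.null(K)) K <- min(1000L, floor(nrow(combined$counts) / 2))
  fc <- cluster_features(combined, K)
  records <- classify_clusters(fc)
  records <- call_high_confidence(records, combined, rho_min, min_presence)
  attr(records, "clustering") <- fc
  records
}
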