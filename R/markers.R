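#' log2(x + 1) transform
#'
#' Applies the log2(counts + 1) transform cell-wise; the inverse
#' \code{2^y - 1} recovers integer counts exactly.
#'
#' @param x A \code{feature_table}.
#' @return A \code{feature_table} of transformed values.
#' @export
log2_transform <- function(x) {
  validate_feature_table(x)
  x$counts <- log2(x$counts + 1)
  x
}

#' Differential microbial abundance between two groups
#'
#' Comparative marker selection: counts are log2(x + 1) transformed, each
#' feature is tested with a two-sample t-test between the two groups, and
#' Benjamini-Hochberg adjustment is applied across all tested features.
#' Features that are all-zero in every sample are excluded before testing
#' (they carry no information and would inflate the BH denominator);
#' a feature with zero variance in both groups and equal means gets p = 1.
#'
#' The effect direction \code{delta} is the group-A minus group-B difference
#' of mean log2 abundance: positive delta means more abundant in group A.
#'
#' @param microbes A \code{feature_table} of raw counts.
#' @param ann Annotation data frame with \code{sample_id} and \code{group};
#'   exactly two groups, each with >= 2 annotated samples.
#' @param alpha FDR threshold for the \code{significant} flag, default 0.05.
#' @param group_a Which group label plays "group A" for the sign of
#'   \code{delta}; default the lexicographically first level.
#' @param variant t-test variant, \code{"student"} (default) or
#'   \code{"welch"}.
#' @return A data frame of class \code{"marker_results"}, one row per tested
#'   feature, sorted by q-value then decreasing |t|: columns
#'   \code{feature_id}, \code{mean_log2_a}, \code{mean_log2_b}, \code{delta},
#'   \code{t_statistic}, \code{p_value}, \code{q_value}, \code{significant}.
#' @export
select_markers <- function(microbes, ann, alpha = 0.05, group_a = NULL,
                           variant = "student") {
  validate_feature_table(microbes)
  ann <- ann[!is.na(ann$group) & ann$sample_id %in% sample_ids(microbes), ]
  groups <- sort(unique(ann$group))
  if (length(groups) != 2L) stop("exactly two groups required")
  if (is.null(group_a)) group_a <- groups[1]
  group_b <- setdiff(groups, group_a)
  ids_a <- ann$sample_id[ann$group == group_a]
  ids_b <- ann$sample_id[ann$group == group_b]
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("each group needs >= 2 samples")
  lg <- log2(microbes$counts + 1)
  nonzero <- rowSums(microbes$counts[, c(ids_a, ids_b), drop = FALSE]) > 0
  if (!all(nonzero))
    message(sum(!nonzero), " all-zero feature(s) excluded before testing")
  lg <- lg[nonzero, , drop = FALSE]
  if (nrow(lg) == 0L) {
    out <- data.frame(feature_id = character(), mean_log2_a = numeric(),
                      mean_log2_b = numeric(), delta = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical())
    class(out) <- c("marker_results", "data.frame")
    return(out)
  }
  res <- t(vapply(rownames(lg), function(f) {
    a <- lg[f, ids_a]; b <- lg[f, ids_b]
    tt <- t_test(a, b, variant)
    c(mean(a), mean(b), tt$statistic, tt$p_value)
  }, numeric(4)))
  out <- data.frame(feature_id = rownames(lg),
                    mean_log2_a = res[, 1], mean_log2_b = res[, 2],
                    delta = res[, 1] - res[, 2],
                    t_statistic = res[, 3], p_value = res[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value <= alpha
  out <- out[order(out$q_value, -abs(out$t_statistic), out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = group_a, b = group_b)
  class(out) <- c("marker_results", "data.frame")
  out
}

#' @export
print.marker_results <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("marker_results: %d features tested (A = %s, B = %s), %d significant\n",
              nrow(x), g[["a"]], g[["b"]], sum(x$significant)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}
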