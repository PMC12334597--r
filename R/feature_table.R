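#' Construct a feature table
#'
#' A feature table holds a non-negative count (or abundance) matrix with
#' features in rows and samples in columns, plus a per-feature kind tag
#' distinguishing host genes from microbial taxa. It is the common currency
#' passed between all pipeline stages.
#'
#' @param counts Numeric matrix, features x samples, with unique rownames
#'   (feature IDs) and unique colnames (sample IDs). All values must be
#'   non-negative and finite.
#' @param kind Either a single string recycled to all features, or a character
#'   vector of length \code{nrow(counts)}; each element must be
#'   \code{"host_gene"} or \code{"microbe"}.
#' @return An object of class \code{"feature_table"}: a list with elements
#'   \code{counts} (the matrix) and \code{kind} (named character vector,
#'   one tag per feature).
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ft <- feature_table(m, "host_gene")
#' dim(ft)
#' @export
feature_table <- function(counts, kind) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have rownames (feature IDs) and colnames (sample IDs)")
  if (length(kind) == 1L) kind <- rep(kind, nrow(counts))
  if (length(kind) != nrow(counts))
    stop("`kind` must have one entry per feature")
  kind <- as.character(kind)
  names(kind) <- rownames(counts)
  x <- structure(list(counts = counts, kind = kind), class = "feature_table")
  validate_feature_table(x)
  x
}

#' Validate a feature table
#'
#' Checks the invariants every feature table must satisfy: unique feature and
#' sample IDs, non-negative finite counts, and a valid kind tag per feature.
#' Called by all constructors; exported so simulated or externally built
#' tables can be checked too.
#'
#' @param x A \code{feature_table}.
#' @return \code{x}, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  counts <- x$counts
  fid <- rownames(counts)
  sid <- colnames(counts)
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (nrow(counts) == 0L) stop("no features")
  if (ncol(counts) == 0L) stop("no samples")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-numeric count at feature '%s', sample '%s'",
                 fid[bad[1, 1]], sid[bad[1, 2]]))
  if (length(x$kind) != nrow(counts) || !identical(names(x$kind), fid))
    stop("kind tags do not align with features")
  if (!all(x$kind %in% c("host_gene", "microbe")))
    stop("kind must be 'host_gene' or 'microbe'")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' @export
print.feature_table <- function(x, ...) {
  kt <- table(factor(x$kind, levels = c("host_gene", "microbe")))
  cat(sprintf("feature_table: %d features (%d host_gene, %d microbe) x %d samples\n",
              nrow(x$counts), kt[["host_gene"]], kt[["microbe"]], ncol(x$counts)))
  invisible(x)
}

#' Feature and sample accessors
#'
#' @param x A \code{feature_table}.
#' @return Character vector of IDs.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read a feature table from a delimited text file
#'
#' Expects a tab-delimited file whose first column holds feature IDs and whose
#' header row holds sample IDs; the body must be numeric and non-negative.
#' Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @param kind Kind tag applied to every feature (\code{"host_gene"} or
#'   \code{"microbe"}).
#' @param sep Field separator, default tab.
#' @return A validated \code{feature_table}.
#' @export
read_feature_table <- function(path, kind, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L) stop("no features in ", path)
  if (ncol(raw) < 2L) stop("no samples in ", path)
  fid <- raw[[1]]
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(fid, colnames(body))))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-numeric cell at row '%s', column '%s' in %s",
                 fid[bad[1, 1]], colnames(num)[bad[1, 2]], path))
  feature_table(num, kind)
}

#' Write a feature table to a delimited text file
#'
#' Inverse of \code{\link{read_feature_table}}: writing then reading returns a
#' table with identical IDs and numerically identical counts.
#'
#' @param x A \code{feature_table}.
#' @param path Output path.
#' @param sep Field separator, default tab.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(x, path, sep = "\t") {
  validate_feature_table(x)
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample PathSeq score tables into one microbial feature table
#'
#' PathSeq emits one tab-delimited score table per sample with (at least) the
#' columns \code{tax_id}, \code{taxonomy}, \code{type}, \code{name},
#' \code{reads}, \code{unambiguous} and \code{score}. This reader restricts
#' each table to rows of the requested taxonomic rank, keys taxa on their
#' \code{name}, and merges across samples; a taxon absent from a sample gets
#' count 0.
#'
#' The default abundance column is \code{unambiguous} (unambiguously assigned
#' read counts, which avoids double-counting multi-mapped reads);
#' \code{score} and \code{reads} are accepted alternatives.
#'
#' @param paths Character vector of file paths, one per sample. Names, if
#'   present, are used as sample IDs; otherwise the file base name (without
#'   extension) is used.
#' @param level Taxonomic rank to retain (matched against the \code{type}
#'   column), default \code{"genus"}.
#' @param value_column Which column to read abundance from:
#'   \code{"unambiguous"}, \code{"score"} or \code{"reads"}.
#' @return A \code{feature_table} of kind \code{"microbe"}, taxa x samples.
#' @export
read_pathseq_scores <- function(paths, level = "genus",
                                value_column = c("unambiguous", "score", "reads")) {
  value_column <- match.arg(value_column)
  if (length(paths) == 0L) stop("no input files")
  sid <- names(paths)
  if (is.null(sid))
    sid <- sub("\\.[^.]*$", "", basename(paths))
  required <- c("type", "name", value_column)
  per_sample <- lapply(seq_along(paths), function(i) {
    tab <- utils::read.table(paths[i], header = TRUE, sep = "\t",
                             check.names = FALSE, quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    miss <- setdiff(required, colnames(tab))
    if (length(miss))
      stop("missing required column(s) in ", paths[i], ": ",
           paste(miss, collapse = ", "))
    tab <- tab[tab$type == level, , drop = FALSE]
    if (anyDuplicated(tab$name))
      stop("conflicting duplicate taxon rows in ", paths[i], ": ",
           paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
    stats::setNames(as.numeric(tab[[value_column]]), tab$name)
  })
  taxa <- unique(unlist(lapply(per_sample, names)))
  if (length(taxa) == 0L)
    stop("no taxa at level '", level, "' in any input file")
  counts <- matrix(0, nrow = length(taxa), ncol = length(paths),
                   dimnames = list(taxa, sid))
  for (i in seq_along(per_sample))
    counts[names(per_sample[[i]]), i] <- per_sample[[i]]
  feature_table(counts, "microbe")
}

#' Read a sample annotation table
#'
#' Reads per-sample clinical metadata from a tab-delimited file with the fixed
#' columns \code{sample_id}, \code{group}, \code{stage}, \code{grade},
#' \code{neoadjuvant}, \code{adjuvant}, \code{radiation}, \code{dfs_time}
#' (months), \code{dfs_event} (0 = censored, 1 = event). Missing clinical
#' fields are allowed; analyses drop incomplete rows listwise.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!"sample_id" %in% colnames(ann)) stop("annotation lacks 'sample_id'")
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation")
  validate_sample_annotation(ann)
  ann
}

#' @rdname read_sample_annotation
#' @param ann A sample annotation data frame.
#' @export
validate_sample_annotation <- function(ann) {
  if ("dfs_event" %in% colnames(ann)) {
    ev <- ann$dfs_event[!is.na(ann$dfs_event)]
    if (!all(ev %in% c(0, 1))) stop("dfs_event must be 0 or 1")
  }
  if ("dfs_time" %in% colnames(ann)) {
    tt <- ann$dfs_time[!is.na(ann$dfs_time)]
    if (any(tt <= 0)) stop("dfs_time must be positive")
  }
  invisible(ann)
}

#' Threshold-filter an externally produced differential-expression table
#'
#' Partitions DE rows into up- and downregulated gene sets using inclusive
#' thresholds on the log2 fold change and the FDR-adjusted p-value:
#' upregulated means \code{l2fc >= l2fc_min} and \code{fdr <= fdr_max};
#' downregulated means \code{l2fc <= -l2fc_min} and \code{fdr <= fdr_max}.
#' Rows failing both are dropped. The two sets are disjoint whenever
#' \code{l2fc_min > 0}.
#'
#' @param de Data frame with columns \code{gene_id}, \code{l2fc}, \code{fdr}.
#' @param l2fc_min Minimum absolute log2 fold change, default 1.
#' @param fdr_max Maximum FDR, default 0.05.
#' @return List with data frames \code{up} and \code{down}.
#' @export
filter_de_table <- function(de, l2fc_min = 1, fdr_max = 0.05) {
  need <- c("gene_id", "l2fc", "fdr")
  miss <- setdiff(need, colnames(de))
  if (length(miss)) stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0,1]")
  keep <- !is.na(de$l2fc) & !is.na(de$fdr)
  up   <- de[keep & de$l2fc >=  l2fc_min & de$fdr <= fdr_max, need, drop = FALSE]
  down <- de[keep & de$l2fc <= -l2fc_min & de$fdr <= fdr_max, need, drop = FALSE]
  list(up = up, down = down)
}
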