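#' Pipeline configuration
#'
#' Configuration for \code{\link{run_pipeline}}. Inputs come either from a
#' simulated cohort (\code{sim} non-NULL) or from files (\code{host_path},
#' \code{microbes_path}, \code{metadata_path}). All randomness flows from the
#' simulation seed.
#'
#' @param sim A \code{\link{sim_config}}, or NULL to read files.
#' @param host_path,microbes_path,metadata_path Input TSV paths (used when
#'   \code{sim} is NULL).
#' @param k_samples Number of MD-Clusters, default 2.
#' @param K Number of feature clusters for integration; NULL uses
#'   min(1000, floor(n_features / 2)).
#' @param rho_min,min_presence High-confidence pair thresholds (0.7, 0.5).
#' @param alpha FDR threshold for marker selection, default 0.05.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = sim_config(), host_path = NULL,
                            microbes_path = NULL, metadata_path = NULL,
                            k_samples = 2, K = NULL, rho_min = 0.7,
                            min_presence = 0.5, alpha = 0.05) {
  if (is.null(sim) &&
      (is.null(host_path) || is.null(microbes_path) || is.null(metadata_path)))
    stop("either `sim` or all three input paths must be given")
  structure(list(sim = sim, host_path = host_path,
                 microbes_path = microbes_path, metadata_path = metadata_path,
                 k_samples = k_samples, K = K, rho_min = rho_min,
                 min_presence = min_presence, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full integrative analysis pipeline
#'
#' Executes, in order: cohort input (simulation or files), MD-Cluster
#' derivation with group association, differential microbial abundance,
#' host-microbe integration with high-confidence pair calling, and survival
#' analysis (log-rank by group and by MD-Cluster; median-split stratification
#' plus a Cox proportional-hazards model for the hazard-linked or best
#' high-confidence feature, adjusted for group, MD-Cluster, stage and
#' radiation).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param quiet Suppress stage progress messages (written to stderr)?
#' @return A list of class \code{"pipeline_report"}; see
#'   \code{\link{write_pipeline_report}} for the serialized bundle.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[micohost] ", ...)

  if (!is.null(config$sim)) {
    say("simulating cohort (seed ", config$sim$seed, ")")
    cohort <- simulate_cohort(config$sim)
    host <- cohort$host; microbes <- cohort$microbes; ann <- cohort$ann
    truth <- cohort$truth
  } else {
    for (p in c(config$host_path, config$microbes_path, config$metadata_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    say("reading input files")
    host <- read_feature_table(config$host_path, "host_gene")
    microbes <- read_feature_table(config$microbes_path, "microbe")
    ann <- read_sample_annotation(config$metadata_path)
    truth <- NULL
  }

  say("deriving MD-Clusters (k = ", config$k_samples, ")")
  clustering <- cluster_samples(relative_abundance(microbes),
                                k = config$k_samples)
  ann$md_cluster <- unname(clustering$labels[ann$sample_id])
  association <- associate_clusters_with_group(clustering, ann)

  say("selecting differential microbes")
  markers <- select_markers(microbes, ann, alpha = config$alpha)

  say("integrating host and microbe features")
  records <- integrate_features(host, microbes, K = config$K,
                                rho_min = config$rho_min,
                                min_presence = config$min_presence)
  class_counts <- table(factor(records$classification,
                               levels = c("host_only", "microbe_only",
                                          "heterologous")))

  say("survival analysis")
  surv <- list(
    by_group = logrank_test(ann$dfs_time, ann$dfs_event, ann$group),
    by_md_cluster = logrank_test(ann$dfs_time, ann$dfs_event, ann$md_cluster))
  target <- if (!is.null(truth) && !identical(truth$hazard_feature, "none")) {
    truth$hazard_feature
  } else {
    hc <- records[records$high_confidence, ]
    if (nrow(hc)) hc$best_gene[which.max(hc$best_rho)] else NA_character_
  }
  if (!is.na(target)) {
    combined <- combine_tables(host, microbes)
    v <- log2(combined$counts[target, ann$sample_id] + 1)
    strat <- stratify_by_median(v, ann$dfs_time, ann$dfs_event)
    covs <- data.frame(abundance_high = as.integer(strat$split == "high"),
                       group = ann$group, md_cluster = ann$md_cluster,
                       stage = ann$stage, radiation = ann$radiation)
    covs <- covs[, vapply(covs, function(x) length(unique(x)) > 1L, TRUE),
                 drop = FALSE]
    surv$median_split <- list(feature = target, test = strat$test,
                              curves = strat$curves)
    surv$cox <- cox_ph(ann$dfs_time, ann$dfs_event, covs)
  }

  structure(list(
    config = config,
    version = as.character(utils::packageVersion("micohost")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    md_cluster = list(labels = clustering$labels,
                      table = association$table,
                      fisher_p = association$p_value),
    markers = markers,
    integration = list(K = attr(records, "clustering")$K,
                       class_counts = as.list(class_counts),
                       records = records,
                       pairs = attr(records, "pairs")),
    survival = surv,
    truth = truth), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  MD-Cluster x group Fisher p = %.4g\n", x$md_cluster$fisher_p))
  cat(sprintf("  markers: %d tested, %d significant\n", nrow(x$markers),
              sum(x$markers$significant)))
  cc <- x$integration$class_counts
  cat(sprintf("  integration: K = %d (%d host_only + %d microbe_only + %d heterologous), %d high-confidence\n",
              x$integration$K, cc$host_only, cc$microbe_only,
              cc$heterologous, sum(x$integration$records$high_confidence)))
  cat(sprintf("  log-rank by group p = %.4g; by MD-Cluster p = %.4g\n",
              x$survival$by_group$p_value, x$survival$by_md_cluster$p_value))
  if (!is.null(x$survival$median_split))
    cat(sprintf("  median split on %s: log-rank p = %.4g\n",
                x$survival$median_split$feature,
                x$survival$median_split$test$p_value))
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Serializes a \code{pipeline_report} to \code{outdir}: \code{report.json}
#' (structured results), \code{md_cluster_labels.tsv}, \code{markers.tsv},
#' \code{pairs.tsv}, and a \code{MANIFEST} listing completed stages. Bodies
#' are byte-identical across runs with the same config and seed.
#'
#' @param report A \code{pipeline_report}.
#' @param outdir Output directory (created if absent).
#' @return \code{outdir}, invisibly.
#' @export
write_pipeline_report <- function(report, outdir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(sample_id = names(report$md_cluster$labels),
                       md_cluster = unname(report$md_cluster$labels))
  utils::write.table(labels, file.path(outdir, "md_cluster_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$markers),
                     file.path(outdir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$integration$pairs, file.path(outdir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    version = report$version,
    seed = report$seed,
    md_cluster = list(
      table = as.vector(report$md_cluster$table),
      fisher_p = report$md_cluster$fisher_p),
    n_markers_significant = sum(report$markers$significant),
    integration = list(K = report$integration$K,
                       class_counts = report$integration$class_counts,
                       n_high_confidence =
                         sum(report$integration$records$high_confidence)),
    survival = list(
      logrank_group_p = report$survival$by_group$p_value,
      logrank_md_cluster_p = report$survival$by_md_cluster$p_value,
      median_split = if (!is.null(report$survival$median_split))
        list(feature = report$survival$median_split$feature,
             logrank_p = report$survival$median_split$test$p_value),
      cox = if (!is.null(report$survival$cox))
        list(converged = report$survival$cox$converged,
             coefficients = report$survival$cox$coefficients)))
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("simulate_or_read", "md_cluster", "markers", "integration",
               "survival", "report"), file.path(outdir, "MANIFEST"))
  invisible(outdir)
}
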