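#' Simulation configuration for a synthetic two-group cohort
#'
#' Bundles and validates every knob of the cohort generator. Defaults mirror
#' a small two-group tumor cohort: 17 + 19 samples, negative-binomial host
#' counts, zero-inflated negative-binomial microbial counts, a handful of
#' group-differential microbes, latent-factor-coupled gene-microbe pairs, and
#' feature-linked proportional-hazards survival with censoring.
#'
#' @param n_group_a,n_group_b Samples per group (defaults 17 and 19).
#' @param n_host_genes,n_microbes Feature counts (defaults 100 and 60).
#' @param n_diff_microbes Microbes whose group-B mean is multiplied by
#'   \code{2^diff_l2fc} (default 5).
#' @param diff_l2fc Planted log2 group effect (default 3).
#' @param n_hetero_pairs Gene-microbe pairs coupled through a shared
#'   per-sample latent factor (default 3).
#' @param pair_loading Latent-factor strength in (0, 1]; both pair members'
#'   negative-binomial means are multiplied by \code{exp(pair_loading * z_j)}
#'   with \code{z_j ~ N(0,1)} (default 1).
#' @param microbe_zero_inflation Probability that a microbial count is masked
#'   to zero (default 0.3), modelling sporadic detection of background taxa.
#'   Planted features (differential microbes and pair members) are exempt:
#'   they emulate the consistently detected taxa that survive presence
#'   filtering and show reproducible group differences.
#' @param nb_dispersion Negative-binomial size parameter (larger = less
#'   overdispersed), default 10.
#' @param library_size_log_sd SD of the log-normal per-sample size factor,
#'   default 0.1 — modest residual depth variation, as found in count tables
#'   that have passed upstream per-sample normalization. A shared size factor
#'   correlates every feature pair, so large values make co-abundance
#'   structure unidentifiable from raw log2 counts.
#' @param hazard_feature Feature whose standardized log2 abundance drives the
#'   hazard: \code{"auto"} (default, the first planted pair's gene), a
#'   feature ID, or \code{"none"}.
#' @param log_hr Log hazard ratio per SD of the hazard feature (default 1).
#' @param baseline_hazard Baseline exponential event rate per month
#'   (default 0.01).
#' @param censor_rate Probability a subject is censored (default 0.4);
#'   censored subjects get a uniform time before their event.
#' @param seed Integer RNG seed (default 1).
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_group_a = 17, n_group_b = 19,
                       n_host_genes = 100, n_microbes = 60,
                       n_diff_microbes = 5, diff_l2fc = 3,
                       n_hetero_pairs = 3, pair_loading = 1,
                       microbe_zero_inflation = 0.3, nb_dispersion = 10,
                       library_size_log_sd = 0.1,
                       hazard_feature = "auto", log_hr = 1,
                       baseline_hazard = 0.01, censor_rate = 0.4,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  with(cfg, {
    stopifnot(n_group_a >= 2, n_group_b >= 2, n_host_genes >= 1,
              n_microbes >= 1, n_diff_microbes >= 0, n_hetero_pairs >= 0,
              pair_loading >= 0, pair_loading <= 1,
              microbe_zero_inflation >= 0, microbe_zero_inflation < 1,
              nb_dispersion > 0, library_size_log_sd >= 0,
              baseline_hazard > 0, censor_rate >= 0, censor_rate < 1)
  })
  if (cfg$n_diff_microbes + cfg$n_hetero_pairs > cfg$n_microbes)
    stop("n_diff_microbes + n_hetero_pairs exceeds n_microbes")
  if (cfg$n_hetero_pairs > cfg$n_host_genes)
    stop("n_hetero_pairs exceeds n_host_genes")
  cfg
}

pad_ids <- function(prefix, n)
  sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))

#' Simulate a synthetic host + microbe cohort with ground truth
#'
#' Generates a host gene count table, a microbial count table, per-sample
#' clinical annotation (group, stage, treatment flags, disease-free survival
#' time and event) and a ground-truth ledger of everything planted:
#' group-differential microbes, latent-factor gene-microbe pairs, and the
#' hazard-linked feature. Fully reproducible from \code{cfg$seed}.
#'
#' Mechanism: host counts are NegBin(mean_g * s_j * pairfactor, size); microbe
#' counts are zero-inflated NegBin with the group-B means of planted
#' differential microbes multiplied by \code{2^diff_l2fc}; each planted pair
#' (g, m) shares a per-sample latent z_j ~ N(0,1) entering both means as
#' \code{exp(pair_loading * z_j)}; survival times are exponential with rate
#' \code{baseline_hazard * exp(log_hr * standardized log2 hazard-feature
#' abundance)}, with independent censoring at rate \code{censor_rate}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of class \code{"sim_cohort"} with elements \code{host} and
#'   \code{microbes} (\code{feature_table}s), \code{ann} (annotation data
#'   frame) and \code{truth} (ground-truth ledger; see Details).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_group_a + cfg$n_group_b
  sid <- pad_ids("S", n)
  group <- rep(c("AA", "EA"), c(cfg$n_group_a, cfg$n_group_b))
  gene_ids <- pad_ids("G", cfg$n_host_genes)
  microbe_ids <- pad_ids("M", cfg$n_microbes)

  diff_ids <- microbe_ids[seq_len(cfg$n_diff_microbes)]
  pair_microbes <- microbe_ids[cfg$n_diff_microbes + seq_len(cfg$n_hetero_pairs)]
  pair_genes <- gene_ids[seq_len(cfg$n_hetero_pairs)]

  s <- exp(stats::rnorm(n, 0, cfg$library_size_log_sd))
  z <- matrix(stats::rnorm(cfg$n_hetero_pairs * n), ncol = n)

  host_mu <- exp(stats::rnorm(cfg$n_host_genes, log(100), 1))
  host_mean <- outer(host_mu, s)
  for (p in seq_len(cfg$n_hetero_pairs))
    host_mean[match(pair_genes[p], gene_ids), ] <-
      host_mean[match(pair_genes[p], gene_ids), ] * exp(cfg$pair_loading * z[p, ])
  host_counts <- matrix(stats::rnbinom(length(host_mean), mu = host_mean,
                                       size = cfg$nb_dispersion),
                        nrow = cfg$n_host_genes,
                        dimnames = list(gene_ids, sid))

  mic_mu <- exp(stats::rnorm(cfg$n_microbes, log(20), 1))
  mic_mean <- outer(mic_mu, s)
  dimnames(mic_mean) <- list(microbe_ids, sid)
  mic_mean[diff_ids, group == "EA"] <-
    mic_mean[diff_ids, group == "EA"] * 2^cfg$diff_l2fc
  for (p in seq_len(cfg$n_hetero_pairs))
    mic_mean[pair_microbes[p], ] <-
      mic_mean[pair_microbes[p], ] * exp(cfg$pair_loading * z[p, ])
  mic_counts <- matrix(stats::rnbinom(length(mic_mean), mu = mic_mean,
                                      size = cfg$nb_dispersion),
                       nrow = cfg$n_microbes,
                       dimnames = list(microbe_ids, sid))
  mask <- matrix(stats::runif(length(mic_counts)) < cfg$microbe_zero_inflation,
                 nrow = cfg$n_microbes)
  mask[microbe_ids %in% c(pair_microbes, diff_ids), ] <- FALSE
  mic_counts[mask] <- 0

  host <- feature_table(host_counts, "host_gene")
  microbes <- feature_table(mic_counts, "microbe")

  hazard_feature <- cfg$hazard_feature
  if (identical(hazard_feature, "auto"))
    hazard_feature <- if (cfg$n_hetero_pairs > 0) pair_genes[1] else "none"
  if (!identical(hazard_feature, "none")) {
    all_counts <- rbind(host_counts, mic_counts)
    if (!hazard_feature %in% rownames(all_counts))
      stop("hazard_feature '", hazard_feature, "' not among simulated features")
    v <- log2(all_counts[hazard_feature, ] + 1)
    vstd <- (v - mean(v)) / stats::sd(v)
    rate <- cfg$baseline_hazard * exp(cfg$log_hr * vstd)
  } else {
    rate <- rep(cfg$baseline_hazard, n)
  }
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < cfg$censor_rate
  dfs_time <- ifelse(censored, stats::runif(n, 0, t_event), t_event)
  dfs_time <- pmax(dfs_time, 0.1)
  dfs_event <- as.integer(!censored)

  ann <- data.frame(
    sample_id = sid,
    group = group,
    stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.75, 0.2, 0.05)),
    grade = sample(c("II/III", "III/III"), n, replace = TRUE,
                   prob = c(0.1, 0.9)),
    neoadjuvant = stats::rbinom(n, 1, 0.25),
    adjuvant = stats::rbinom(n, 1, 0.8),
    radiation = stats::rbinom(n, 1, 0.6),
    dfs_time = dfs_time,
    dfs_event = dfs_event,
    md_cluster = NA_integer_,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    diff_microbes = data.frame(id = diff_ids,
                               l2fc = rep(cfg$diff_l2fc,
                                          cfg$n_diff_microbes),
                               stringsAsFactors = FALSE),
    hetero_pairs = data.frame(gene = pair_genes, microbe = pair_microbes,
                              loading = rep(cfg$pair_loading,
                                            cfg$n_hetero_pairs),
                              stringsAsFactors = FALSE),
    hazard_feature = hazard_feature,
    log_hr = cfg$log_hr,
    group = stats::setNames(group, sid)), class = "sim_truth")

  structure(list(host = host, microbes = microbes, ann = ann, truth = truth,
                 config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d + %d samples, %d host genes, %d microbes (%d differential, %d planted pairs)\n",
    x$config$n_group_a, x$config$n_group_b, x$config$n_host_genes,
    x$config$n_microbes, nrow(x$truth$diff_microbes),
    nrow(x$truth$hetero_pairs)))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes \code{host.tsv}, \code{microbes.tsv}, \code{metadata.tsv} and
#' \code{truth.json} into \code{outdir}.
#'
#' @param sim A \code{sim_cohort}.
#' @param outdir Output directory (created if absent).
#' @return \code{outdir}, invisibly.
#' @export
write_cohort <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(sim$host, file.path(outdir, "host.tsv"))
  write_feature_table(sim$microbes, file.path(outdir, "microbes.tsv"))
  utils::write.table(sim$ann, file.path(outdir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(diff_microbes = sim$truth$diff_microbes,
         hetero_pairs = sim$truth$hetero_pairs,
         hazard_feature = sim$truth$hazard_feature,
         log_hr = sim$truth$log_hr),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Monte-Carlo expected Spearman correlation of a planted pair
#'
#' Estimates the population Spearman correlation induced between the two
#' members of a planted gene-microbe pair by the shared latent factor, under
#' the generator's count mechanism. Used to choose loadings that land above
#' or below a correlation threshold of interest.
#'
#' @param pair_loading Latent-factor strength.
#' @param nb_dispersion Negative-binomial size parameter, default 10.
#' @param zero_inflation Zero-inflation probability applied to the microbe
#'   member, default 0 (matching the generator, which exempts pair members).
#' @param n Monte-Carlo sample size, default 20000.
#' @param seed RNG seed, default 1.
#' @return Estimated Spearman rho.
#' @export
expected_pair_rho <- function(pair_loading, nb_dispersion = 10,
                              zero_inflation = 0, n = 20000, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  g <- stats::rnbinom(n, mu = 100 * exp(pair_loading * z), size = nb_dispersion)
  m <- stats::rnbinom(n, mu = 20 * exp(pair_loading * z), size = nb_dispersion)
  m[stats::runif(n) < zero_inflation] <- 0
  if (stats::sd(g) == 0 || stats::sd(m) == 0) return(0)
  stats::cor(g, m, method = "spearman")
}
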