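test_that("combine_tables aligns samples and enforces disjoint features", {
  host <- tiny_table(1:10, nf = 5, ns = 2, kind = "host_gene", prefix = "g")
  mic <- tiny_table(1:6, nf = 3, ns = 2, kind = "microbe", prefix = "m")
  comb <- combine_tables(host, mic)
  expect_equal(nrow(comb$counts), 8)
  expect_identical(as.vector(table(comb$kind)[c("host_gene", "microbe")]),
                   c(5L, 3L))

  # permuted microbe sample columns give the same combined matrix
  micp <- mic
  micp$counts <- micp$counts[, c("s2", "s1")]
  expect_identical(combine_tables(host, micp)$counts, comb$counts)

  clash <- tiny_table(1:6, nf = 3, ns = 2, kind = "microbe", prefix = "g")
  expect_error(combine_tables(host, clash), "collision")
  extra <- mic
  colnames(extra$counts) <- c("s1", "s9")
  expect_error(combine_tables(host, extra), "s9")
})

test_that("cluster_features separates correlation blocks and is invariant", {
  set.seed(81)
  n <- 20
  u <- stats::rnorm(n)
  # block 1: 3 features monotone in u; block 2: 3 features monotone in -u
  m <- rbind(u, 2 * u + 1, exp(u), -u, 1 - u, exp(-u)) + 100
  dimnames(m) <- list(c("g1", "g2", "g3", "m1", "m2", "m3"),
                      sprintf("s%02d", 1:n))
  ft <- feature_table(abs(m), c(rep("host_gene", 3), rep("microbe", 3)))
  fc <- cluster_features(ft, K = 2)
  expect_equal(length(unique(fc$assignment[1:3])), 1)
  expect_equal(length(unique(fc$assignment[4:6])), 1)
  expect_false(fc$assignment[["g1"]] == fc$assignment[["m1"]])

  # K = n_features gives singletons
  single <- cluster_features(ft, K = 6)
  expect_equal(sort(unname(single$assignment)), 1:6)

  # deterministic under sample-column permutation
  perm <- sample(colnames(ft$counts))
  ftp <- ft
  ftp$counts <- ftp$counts[, perm]
  expect_identical(cluster_features(ftp, K = 2)$assignment, fc$assignment)

  expect_error(cluster_features(ft, K = 7), "exceeds")
  cft <- ft
  cft$counts[2, ] <- 3
  expect_warning(fc2 <- cluster_features(cft, K = 2), "constant")
  expect_identical(fc2$dropped, "g2")
})

test_that("classify_clusters partitions K and matches a brute-force recount", {
  set.seed(91)
  nfeat <- 200; K <- 40
  kinds <- stats::setNames(sample(c("host_gene", "microbe"), nfeat, TRUE),
                           paste0("f", seq_len(nfeat)))
  assignment <- stats::setNames(sample(seq_len(K), nfeat, TRUE), names(kinds))
  rec <- classify_clusters(assignment, kinds)
  expect_equal(nrow(rec), length(unique(assignment)))
  expect_equal(sum(rec$n_host + rec$n_microbe), nfeat)
  for (i in seq_len(nrow(rec))) {
    members <- kinds[names(assignment)[assignment == rec$cluster_id[i]]]
    want <- if (any(members == "host_gene") && any(members == "microbe"))
      "heterologous" else if (all(members == "host_gene"))
      "host_only" else "microbe_only"
    expect_identical(rec$classification[i], want)
    expect_equal(rec$n_host[i], sum(members == "host_gene"))
  }
  # the three classes partition the clusters on any input
  expect_equal(sum(table(rec$classification)), nrow(rec))

  expect_identical(classify_clusters(stats::setNames(c(1, 1), c("a", "b")),
                                     c(a = "host_gene", b = "host_gene"))$classification,
                   "host_only")
  expect_identical(classify_clusters(stats::setNames(c(1, 1), c("a", "b")),
                                     c(a = "host_gene", b = "microbe"))$classification,
                   "heterologous")
})

test_that("the presence gate blocks pairs regardless of correlation", {
  set.seed(101)
  n <- 20
  u <- stats::rnorm(n)
  g <- exp(u) * 50
  m_dense <- exp(u) * 20
  m_sparse <- m_dense
  m_sparse[sample(n, 13)] <- 0          # non-zero in only 35% of samples
  counts <- rbind(gene = g, dense = m_dense, sparse = m_sparse)
  colnames(counts) <- sprintf("s%02d", 1:n)
  ft <- feature_table(counts, c("host_gene", "microbe", "microbe"))
  rec <- classify_clusters(stats::setNames(c(1, 1, 2), rownames(counts)),
                           ft$kind)
  rec <- call_high_confidence(rec, ft, rho_min = 0.7, min_presence = 0.5)
  expect_true(rec$high_confidence[rec$cluster_id == 1])
  expect_identical(rec$best_microbe[rec$cluster_id == 1], "dense")

  # the same gene with only the sparse microbe fails the gate even at rho ~ 1
  rec2 <- classify_clusters(stats::setNames(c(1, 2, 1), rownames(counts)),
                            ft$kind)
  rec2 <- call_high_confidence(rec2, ft, rho_min = 0.7, min_presence = 0.5)
  i <- which(rec2$cluster_id == 1)
  expect_false(rec2$presence_ok[i])
  expect_false(rec2$high_confidence[i])
})

test_that("high-confidence calls are monotone in rho_min and min_presence", {
  sim <- simulate_cohort(sim_config(seed = 13))
  combined <- log2_transform(combine_tables(sim$host, sim$microbes))
  fc <- suppressWarnings(cluster_features(combined, K = 32))
  rec <- classify_clusters(fc)
  n_hc <- function(rho_min, min_presence)
    sum(call_high_confidence(rec, combined, rho_min,
                             min_presence)$high_confidence)
  base <- n_hc(0.7, 0.5)
  expect_lte(n_hc(0.8, 0.5), base)
  expect_lte(n_hc(0.7, 0.7), base)
  expect_gte(n_hc(0.5, 0.5), base)
  expect_gte(n_hc(0.7, 0.2), base)
})

test_that("integrate_features recovers planted pairs end-to-end", {
  sim <- simulate_cohort(sim_config(seed = 17))
  rec <- suppressWarnings(suppressMessages(
    integrate_features(sim$host, sim$microbes, K = 32)))
  truthp <- paste(sim$truth$hetero_pairs$gene, sim$truth$hetero_pairs$microbe)
  called <- rec[rec$high_confidence, ]
  callp <- paste(called$best_gene, called$best_microbe)
  expect_true(all(truthp %in% callp))
  expect_true(all(called$best_rho > 0.7))
  # class counts partition K
  expect_equal(nrow(rec), attr(rec, "clustering")$K)
  # the detail pair list contains every flagged best pair
  pairs <- attr(rec, "pairs")
  expect_true(all(callp %in% paste(pairs$gene, pairs$microbe)))
})
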