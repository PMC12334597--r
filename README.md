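# micohost

Integrative analysis of the tumor microbiome and the host transcriptome in
small two-group cancer cohorts.

Bulk RNA-seq of tumor tissue captures two signals at once: host gene
expression and transcripts of intratumoral microbes (recoverable with a
computational-subtraction pipeline such as PathSeq). `micohost` implements
the downstream analysis that links the two, aimed at studies comparing
patient groups — for example tumors from women of African versus European
ancestry in triple-negative breast cancer — on cohorts of a few dozen
samples:

1. **Microbe-derived sample clusters (MD-Clusters).** Samples are clustered
   on relative microbial abundance with average-linkage hierarchical
   clustering under the distance d(i,j) = 1 − ρ(i,j), where ρ is the
   Spearman rank correlation of the two samples' abundance profiles. The
   association between the resulting clusters and the patient group is
   tested with Fisher's exact test on the 2×2 cluster × group table.
2. **Differential microbial abundance.** Each taxon's counts are
   log2(x + 1)-transformed and compared between groups with two-sample
   t-tests; Benjamini–Hochberg adjustment controls the FDR across taxa at
   q ≤ 0.05.
3. **Host-gene–microbe integration.** Host genes and microbes are combined
   into one matrix, features are hierarchically clustered (Spearman distance,
   average linkage) into K clusters, clusters containing only one feature
   kind (homologous) are set aside, and *heterologous* clusters — at least
   one host gene and one microbe — are screened for high-confidence pairs:
   a cross-kind pair with Spearman ρ > 0.7 whose members are both non-zero
   in ≥ 50% of samples.
4. **Survival stratification.** Disease-free survival is analysed with
   Kaplan–Meier curves, two-group log-rank tests, median splits (high =
   above the cohort median) on any feature, and Cox proportional-hazards
   models (Breslow ties) adjusting for group, MD-Cluster, stage and
   treatment.

Because cohorts like this are small and not freely redistributable, the
package ships a synthetic cohort generator (`simulate_cohort()`) that plants
the statistical structure the analysis assumes — negative-binomial host
counts, zero-inflated negative-binomial microbial counts, group-differential
microbes, latent-factor-coupled gene–microbe pairs, and a hazard-linked
feature — together with a ground-truth ledger, so every stage is testable
end to end.

## Worked example

```r
library(micohost)

report <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)),
                       quiet = TRUE)
print(report)
#> pipeline_report
#>   MD-Cluster x group Fisher p = 0.2159
#>   markers: 60 tested, 5 significant
#>   integration: K = 80 (36 host_only + 15 microbe_only + 29 heterologous), 3 high-confidence
#>   log-rank by group p = 0.6126; by MD-Cluster p = 0.4143
#>   median split on G001: log-rank p = 0.0006594

head(as.data.frame(report$markers), 5)
#>   feature_id mean_log2_a mean_log2_b delta t_statistic  p_value  q_value significant
#> 1        M02        3.95        6.90 -2.96       -19.0 1.17e-19 7.00e-18        TRUE
#> 2        M03        4.18        7.29 -3.11       -17.7 1.07e-18 3.20e-17        TRUE
#> 3        M05        4.55        7.82 -3.27       -17.3 1.98e-18 3.96e-17        TRUE
#> 4        M04        2.95        5.90 -2.96       -15.8 3.07e-17 4.61e-16        TRUE
#> 5        M01        4.19        6.92 -2.73       -15.0 1.50e-16 1.80e-15        TRUE
```

The default synthetic cohort (17 + 19 samples) plants five differential
microbes (M01–M05, 8-fold higher in group EA) and three gene–microbe pairs.
All five planted microbes are recovered at q ≤ 0.05 with negative `delta`
(delta is the AA-minus-EA difference of mean log2 abundance, so a negative
value means higher abundance in EA). The integration calls exactly the three
planted pairs high-confidence, and the median split on the hazard-linked
gene G001 shows the planted survival effect (log-rank p ≈ 7e-4). The Fisher
p of 0.22 for MD-Cluster × group reflects that five differential microbes
among sixty only partially separate the groups at n = 36 — cluster/group
association is a weaker signal than per-taxon differential abundance.

Individual stages are available as plain functions operating on
`feature_table` objects read from TSV (`read_feature_table()`,
`read_pathseq_scores()`, `read_sample_annotation()`): see
`relative_abundance()`, `cluster_samples()`,
`associate_clusters_with_group()`, `select_markers()`,
`integrate_features()`, `km_fit()`, `logrank_test()`, `median_split()`,
`cox_ph()`, and `stratify_by_median()`.

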