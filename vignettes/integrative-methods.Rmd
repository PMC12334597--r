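---
title: "Methods: integrative microbiome–transcriptome analysis with micohost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative microbiome–transcriptome analysis with micohost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micohost)
```

`micohost` analyses paired count matrices from bulk tumor RNA-seq — host
gene expression and microbial transcript abundance — for small two-group
cohorts, and ties both to disease-free survival (DFS). This vignette is the
package's own account of the statistical procedures, the choices behind
them, and what the bundled synthetic cohorts can and cannot demonstrate.

## Data model

A `feature_table` is a non-negative matrix of features × samples where each
feature is tagged `host_gene` or `microbe`. Host counts are gene-level
expression counts; microbial counts are per-taxon transcript read counts at
a fixed taxonomic rank (genus by default), as produced by a
computational-subtraction classifier such as PathSeq. Only the classifier's
tabular per-sample score files are consumed (`read_pathseq_scores()`); the
upstream alignment stages are out of scope. PathSeq offers three candidate
abundance columns; the reader defaults to `unambiguous` read counts because
ambiguous multi-mapped reads would otherwise be counted toward several taxa
at once, and taxa are keyed on their `name` so merged tables match
genus-level reporting. Both `score` and `reads` remain selectable.

Clinical annotation carries the group label (e.g. AA/EA ancestry), stage,
grade, treatment flags, and DFS time in months with an event indicator
(1 = death or confirmed disease, 0 = censored). Missing clinical fields are
permitted and handled listwise per analysis, since per-variable denominators
in real cohort tables differ.

## Microbe-derived sample clusters

`cluster_samples()` clusters samples on **relative** microbial abundance
(columns scaled to proportions) using the distance d = 1 − ρ with ρ the
Spearman correlation between two samples' profiles, agglomerated by average
linkage and cut to k = 2 clusters by default (the two-major-cluster
structure typical of these cohorts; finer sub-cluster structure remains
accessible through the stored merge history rather than extra labels). We
use 1 − ρ rather than (1 − ρ)/2: linkage and cuts depend only on the
ordering of distances, but heights are then directly interpretable as
correlation deficits. Cluster labels are assigned 1..k by decreasing size,
with ties broken by the smallest member sample ID, making the labelling
deterministic and permutation-invariant.

Features constant across all samples carry no rank information and are
dropped with a warning; a sample whose profile is constant across the
retained features has no defined Spearman correlation and is an error rather
than something to guess around.

`associate_clusters_with_group()` tests the 2×2 cluster × group table with
Fisher's exact test. The two-sided p-value uses the point-probability rule —
the sum of hypergeometric probabilities of all margin-consistent tables no
more probable than the observed one. Other two-sided conventions (doubling
the one-sided tail) exist and give different answers on asymmetric margins;
the point-probability rule is the one used throughout.

## Differential microbial abundance

`select_markers()` mirrors comparative marker selection as done in heatmap
tools such as Morpheus: counts are transformed to log2(x + 1), each taxon is
tested with a two-sample t-test between groups, and Benjamini–Hochberg
adjustment is applied across taxa, flagging q ≤ 0.05. Three conventions are
explicit:

* **Raw counts, not relative abundance.** The transform applies to the
  count matrix itself; only the sample-clustering step uses proportions.
  Consequently a global rescaling of one sample's counts shifts its log2
  values — there is no hidden normalisation — and the synthetic generator
  keeps residual depth variation small for exactly this reason (below).
* **Pooled-variance (Student) t-test by default**, with Welch available by
  argument. The pooled test is what standard marker-selection tools apply;
  the package exposes both because neither dominates at n ≈ 18 per group.
* **Direction.** `delta` = mean log2 in group A minus group B, with group A
  defaulting to the lexicographically first label and overridable — sign
  conventions are a classic source of silent errors in two-group
  comparisons.

Features that are zero in every sample are removed before testing (they are
untestable and would only enlarge the BH denominator); a feature with zero
variance in both groups and equal means is assigned p = 1. The BH
implementation is the classical step-up rule; rejecting q ≤ α reproduces the
step-up rejection set exactly, which the test suite verifies against an
independent oracle.

## Host–microbe integration

`integrate_features()` combines the two matrices (samples aligned, feature
IDs disjoint), applies log2(x + 1) so host and microbial scales coexist
(Spearman correlation is monotone-invariant, so this choice affects stored
values but not the clustering), and hierarchically clusters **features**
with the same Spearman/average-linkage recipe, cut into K clusters.

K defaults to min(1000, ⌊n_features/2⌋): K = 1000 is the standard operating
point for transcriptome-scale matrices (tens of thousands of features), and
the fallback keeps the cut well-defined on the smaller matrices used in
simulation and testing.

Clusters are classified by membership: `host_only` and `microbe_only`
(homologous) versus `heterologous` (at least one of each). The three counts
always partition K. Within each heterologous cluster,
`call_high_confidence()` evaluates every cross-kind pair whose **both**
members are non-zero in ≥ 50% of samples — the presence filter is applied
per pair member, the most conservative reading that still yields per-pair
calls — and flags the cluster high-confidence when the best eligible pair's
Spearman ρ exceeds 0.7. Ties are broken lexicographically so results are
reproducible; all eligible pairs and their correlations are retained in a
detail table, since a single cluster often contains several reportable
pairs. The high-confidence set is monotone non-increasing in both
thresholds, which the suite checks.

Correlations are computed on the log2-transformed combined matrix. Whether
one computes them on raw counts, proportions, or transformed values changes
nothing for Spearman within a sample set, so this is recorded for
reproducibility rather than as a substantive choice.

## Survival

`km_fit()` is the product-limit estimator; `logrank_test()` the two-group
log-rank chi-square (df = 1) with hypergeometric variance per event time;
`median_split()` dichotomises a feature at the cohort median with **ties
assigned to low** — at n ≈ 36 with sparse microbial abundances, ties at the
median are common, and an explicit rule keeps the split deterministic
(`high` means strictly above the median). `cox_ph()` maximises the Breslow
partial likelihood, the simplest defensible tie convention; monotone
likelihood (separation) is detected and reported as a non-converged fit with
no hazard ratios rather than as spuriously huge ones. Abundance can enter
the Cox model either as the high/low indicator or as a continuous
standardized value; the pipeline uses the median-split indicator, matching
the stratified Kaplan–Meier display it accompanies.

## The synthetic cohort generator

`simulate_cohort()` generates cohorts with the structure the analysis
assumes, plus a ground-truth ledger. Defaults are fixed at the study
conditions the package targets and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_group_a`, `n_group_b` | 17, 19 | cohort sizes (AA, EA) |
| `n_host_genes`, `n_microbes` | 100, 60 | feature counts (desk-scale) |
| `n_diff_microbes`, `diff_l2fc` | 5, 3 | planted group effect: group-B mean × 2³ |
| `n_hetero_pairs`, `pair_loading` | 3, 1.0 | latent-factor gene–microbe pairs |
| `microbe_zero_inflation` | 0.3 | Bernoulli zero mask on background taxa |
| `nb_dispersion` | 10 | NB size for host and microbe counts |
| `library_size_log_sd` | 0.1 | residual per-sample depth variation |
| `log_hr`, `baseline_hazard` | 1, 0.01/month | hazard on the linked feature |
| `censor_rate` | 0.4 | fraction censored |

Host counts are NegBin(μ_g · s_j, size) with a log-normal sample size factor
s_j; microbial counts are zero-inflated NegBin. Each planted pair (gene g,
microbe m) shares a per-sample latent z_j ~ N(0,1) entering both means
multiplicatively as exp(loading · z_j) — the simplest mechanism that
produces rank correlation robust to the log2 transform. Survival times are
exponential with rate `baseline_hazard · exp(log_hr · standardized log2
abundance)` of the hazard feature (by default the first planted pair's
gene), with independent censoring.

Three generator decisions deserve emphasis because they determine what the
planted structure can show:

* **Zero inflation applies to background microbes only.** A Bernoulli zero
  mask on a planted feature destroys the very signal being planted: masking
  30% of a taxon's counts inflates its within-group log2 variance so much
  that an 8-fold group effect drops to t ≈ 2.6 at n = 17/19, and caps the
  achievable pair correlation near 0.5 regardless of loading. The planted
  differential microbes and pair members model the *consistently detected*
  taxa — the kind that pass the ≥ 50% presence filter and replicate across
  samples — while the mask models sporadic detection of background taxa,
  which is the phenomenon the presence filter exists to exclude.
* **Depth variation is modest (log-sd 0.1).** A shared per-sample size
  factor correlates *every* feature pair (at log-sd 0.3 the induced
  background Spearman ρ is ≈ 0.45 between high-abundance features), which
  would make co-abundance structure unidentifiable from raw log2 counts.
  Count tables entering this kind of analysis have passed per-sample
  normalisation upstream; 0.1 models what remains.
* **Loading calibration is computed, not assumed.** `expected_pair_rho()`
  Monte-Carlo-estimates the population Spearman ρ a loading induces under
  the count mechanism (≈ 0.86 at loading 1.0 with the default dispersion),
  so tests that need pairs above or below the 0.7 threshold choose loadings
  from the mechanism itself.

What the generator does **not** emulate: taxonomic hierarchies and
classification noise, compositional coupling between taxa, FFPE artifacts,
batch effects, heavy-tailed library sizes, or correlated censoring. Passing
tests on these cohorts therefore demonstrate that the pipeline recovers the
structure it targets when that structure is present and stays quiet when it
is absent — not that real tumor cohorts contain such structure, nor that
the method is robust to every artifact of real data.

## Numerical conventions and degenerate inputs

* Chi-square with Yates correction subtracts min(0.5, |O − E|) from each
  |O − E|, so the corrected statistic clamps at 0 (and p at 1) instead of
  overshooting past independence — visible on nearly-independent 2×2 tables.
* The Wilcoxon rank-sum test enumerates the exact permutation distribution
  of the rank sum (ties included) when n₁ + n₂ ≤ 12 and otherwise uses the
  normal approximation with tie-corrected variance and continuity
  correction; the two agree within 0.02 at the crossover.
* All-tied Wilcoxon input, both-groups-constant-and-equal t-test input, and
  zero-margin Fisher tables return p = 1 by convention; zero pooled variance
  with unequal means is an error.
* p-values are kept at full precision; rounding happens only in display.
* All pipeline randomness flows from the single simulation seed; every
  stage is deterministic given its input, and report bodies are
  byte-identical across reruns.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to finish
comfortably on one CPU while keeping each check statistically meaningful:
cohorts of 36 samples with 100 genes + 60 microbes; 20-seed replications for
recovery metrics; 500 replicates for calibration checks (log-rank type-I
error, null pair correlations); Cox recovery at n = 200; enumeration oracles
at n ≤ 30 per table. K = 32 (≈ n_features/5) is used for integration
recovery runs so clusters average a handful of features, matching the
regime in which heterologous clusters are interpretable.

## Known limitations

* Feature clustering at transcriptome scale (tens of thousands of features)
  builds a dense correlation matrix; beyond ~20k features memory becomes the
  binding constraint.
* The r×c Fisher test is not implemented; 2×c tables use the chi-square.
* Cox diagnostics (proportionality, time-varying effects) are out of scope;
  the model reports Wald statistics only.
* With k = 2 MD-Clusters the group-association test is exact; for k > 2 no
  association test is provided.
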