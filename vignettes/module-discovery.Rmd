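---
title: "Per-patient gene module discovery: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-patient gene module discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulomics)
```

## The problem and the model

Multi-omics cohorts describe each patient with several genes × samples
matrices: expression abundance, copy-number log-ratios or calls,
methylation beta values in [0, 1], and 0/1 mutation indicators.
`modulomics` asks a patient-level question: which groups of genes share a
common genomic configuration *within one individual*, and which of those
groups contain drug targets? Each patient is analysed independently — no
information is shared across samples, so a module found in patient A makes
no claim about patient B.

After alignment (intersection of gene symbols and sample ids across layers,
lexicographic order, exact case-sensitive matching) each patient *i* is
reduced to a matrix **M**~i~ = (G × m): one row per gene of the analysis
gene set *G*, one column per omics layer. Layers are always ordered
(expression, copy number, methylation, mutation, other) so the column order
of **M**~i~ does not depend on how the files were passed in.

### Strategy M1: unsupervised random-forest proximity + k-means

A random forest is trained to discriminate the real rows of **M**~i~ from a
synthetic class obtained by independently permuting each column — the
classical product-of-marginals construction, as implemented by the
`randomForest` package in unsupervised mode. Because the synthetic class
destroys the joint structure but preserves the marginals, trees split on
whatever dependence structure the real genes share, and the resulting
gene–gene proximity — the fraction of trees in which two genes fall in the
same terminal node — acts as a similarity measure that is indifferent to
the scale and type of the individual layers. Proximity is accumulated over
*all* trees (not out-of-bag cases only), which makes it exactly 1 for genes
with identical feature rows; this property is asserted in the tests.

Genes are then clustered by k-means on the *rows* of the proximity matrix:
each gene is represented by its proximity profile to every gene, and
Euclidean k-means is applied directly to those profiles. We deliberately
cluster the proximity itself rather than converting it to a dissimilarity
and using a medoid method, keeping the clustering step a plain k-means as
the interface promises. `stats::kmeans` (Hartigan–Wong) is used with
multiple random restarts and `iter.max = 300`; on every small instance we
enumerated (n = 8 genes, k = 2, 50 restarts) it attains the exhaustive
partition optimum of the within-cluster sum of squares, which is the
behaviour the restart count is chosen for.

### Choosing k: silhouette analysis

When `k = "auto"`, `select_k_silhouette()` clusters for every k in a range
(default 2 … min(10, |G| − 1)) and keeps the k with the largest mean
silhouette width, computed with `cluster::silhouette` on the Euclidean
distances between proximity rows. Ties break toward the smaller k:
parsimony is preferred when two cluster counts explain the geometry equally
well. When a candidate k exceeds the number of distinct proximity profiles
(perfectly block-structured matrices), the effective k is reduced with a
message, so degenerate ideal inputs do not abort the search.

### Strategy M2: logic rules + k-modes

The second strategy binarizes each patient's profile with crisp logic
rules, producing a g × r binary matrix. The seven default rules are:

| rule | layer | condition | default | sign |
|---|---|---|---|---|
| over_expressed | expression | z > threshold | +1 | activating |
| under_expressed | expression | z < threshold | −1 | suppressing |
| cn_gain | copy number | value > threshold | +0.3 | activating |
| cn_loss | copy number | value < threshold | −0.3 | suppressing |
| hyper_methylated | methylation | beta > threshold | 0.7 | suppressing |
| hypo_methylated | methylation | beta < threshold | 0.3 | activating |
| mutated | mutation | value ≥ threshold | 1 | activating |

Expression rules act on the within-patient z-score across genes — a
scale-free criterion that works for counts, TPM or microarray intensities
alike — while copy-number and methylation rules act on raw values with the
conventional ±0.3 log-ratio and 0.3/0.7 beta cut-offs, and would be
destroyed by standardization. All thresholds are overridable
(`default_rules(list(cn_gain = 0.5))` or a rule TSV on the command line),
and only rules whose layer was actually provided are applied, so a
two-layer analysis simply has fewer rule columns. Inequalities are strict
for above/below; `mutated` uses ≥ so that mutation counts also work. The
rules are crisp 0/1 decisions by design: the downstream clustering and
scores consume binary evidence, and fuzzy membership would add a free
parameter (the membership function) without changing which genes co-cluster
at these cohort sizes.

The binary matrix is clustered with Huang's k-modes, written in-package:
dissimilarity is the Hamming distance over rule columns, centroids are
per-column modes, and assignment/update iterate to convergence. Details
that make the procedure deterministic given a seed: initial centroids are
distinct rows sampled per restart; mode ties (a column with equally many 0s
and 1s) keep the current centroid value, or 0 at initialization; an empty
cluster is re-seeded by moving its centroid onto the point farthest from
its own centroid, which cannot increase the objective, so the per-iteration
cost trace is monotone non-increasing (asserted in tests); the best of
`n_init` restarts by total within-cluster dissimilarity wins. If fewer than
k distinct rows exist, the effective k is reduced and reported. With 50
restarts on instances small enough to enumerate (g ≤ 8), the attained cost
equals the exhaustive optimum over all partitions.

k for k-modes is always user-specified; silhouette selection is offered
only for the proximity strategy, where the clustered objects live in a
continuous space with a natural Euclidean distance.

## Scores and automatic selection

Module scores are defined in-package as:

* `score_genes` — mean of the binary rule matrix over module genes ×
  applied rules (overall alteration density, in [0, 1]);
* `score_drugs` — fraction of module genes with at least one association in
  the gene–drug table (in [0, 1]); the count of distinct attached drugs is
  reported separately as `n_drugs`;
* per-rule sub-scores `sub_<rule>` — column means over module genes;
* `s_score` — mean of the activating sub-scores minus mean of the
  suppressing sub-scores, each mean taken over the rule columns present; a
  signed summary in [−1, 1] where +1 means every gene passes every
  activating rule and no suppressing one.

The signed form lets one selection rule serve both directions: per patient,
among modules with ≥ `min_drugs` drugs, the extremal `s_score` wins
(maximal for `direction = "active"`, minimal for `"inactive"`), with ties
broken by larger `score_drugs` and then smaller module index, and a
fallback to the overall best module when no module meets the drug
constraint. The category is AOMD (active, druggable, `s_score` > 0), IOMD
(inactive, druggable, `s_score` < 0), or AOM/none otherwise. This policy is
total and deterministic, and the tests verify it against an exhaustive
per-patient rescan. `min_drugs` defaults to 1 — a module with a single
actionable gene is already clinically interesting.

For proximity-strategy runs the rule matrix is computed with the same
default rules purely for scoring, so both strategies share one scoring
path and their outputs are directly comparable.

## The synthetic cohort generator

`generate_cohort()` emulates the regime the method is designed for:
a cohort in which each patient carries gene groups with concordant
alteration states across layers. Genes are partitioned into `n_modules`
modules (module 1 activated, module 2 suppressed, further modules neutral —
a fixed assignment so that every cohort contains exactly one planted
activated module for detection-rate experiments). Per layer:

* activated: expression ~ N(+δ, 1), copy number ~ N(+0.6, 0.15),
  methylation ~ Beta(mean 0.2, concentration 10), mutation ~ Bernoulli(0.3);
* suppressed: expression ~ N(−δ, 1), copy number ~ N(−0.6, 0.15),
  methylation ~ Beta(mean 0.8); mutation stays at the background
  Bernoulli(0.02) — mutation is an activation signal, and a suppressed
  module is not hypermutated;
* neutral: expression ~ N(0, 1), copy number ~ N(0, 0.1), methylation ~
  Beta(mean 0.5), mutation ~ Bernoulli(0.02);

with δ = 3 / 1.5 / 0.5 for strong / moderate / weak effects. Beta draws use
a fixed concentration of 10, keeping beta values in [0, 1] by construction.
Module composition is shared cohort-wide by default (each patient carries
the same partition, differing only in noise); `per_patient_modules = TRUE`
re-partitions independently per patient, since the method itself clusters
each patient independently and both regimes must be testable. A
`druggable_fraction` of genes (default 0.3) receives 1–3 synthetic drug
names.

What the generator does *not* emulate: realistic marginal distributions of
real tumour data, copy-number segment structure (genes are drawn
independently), batch effects, and partial module membership. Passing the
recovery experiments therefore shows that the pipeline recovers planted
concordant structure at the stated effect sizes — not that real cohorts
contain such structure.

One consequence of the generator's own design is worth stating: with a
third of genes activated at +δ and a third suppressed at −δ, the
within-patient expression z-score has standard deviation ≈ √(1 + 2δ²/3)
(≈ 2.6 at δ = 3), so even strongly activated genes pass the z > 1 rule at a
rate of about 1 − Φ(√7 − 3) ≈ 0.64, not near 1. The test suite asserts this
closed-form rate rather than a naive expectation; module recovery does not
suffer, because the clustering uses all rule columns jointly.

## Numerical and design choices

* **Determinism.** Every stochastic step (forest, k-means, k-modes,
  generator) is seeded; cohort runs derive per-patient seeds as
  `seed + patient index`, so per-patient results are independent of
  processing order and a rerun is byte-identical.
* **Canonical labels.** Module indices are relabelled so module 1 contains
  the lexicographically first gene; outputs are comparable across runs and
  methods.
* **Standardization.** Continuous columns of **M**~i~ are z-scored across
  genes before the forest (constant columns map to all-zero); binary
  mutation columns are left as indicators. Without this, layers on large
  scales dominate tree splits. `standardize = FALSE` disables it.
* **Forest defaults.** `n_trees = 500`, `mtry = max(1, ⌊√m⌋)` — the
  customary defaults; with m ≤ 5 features per gene, deeper forests change
  proximities negligibly.
* **Missing values.** Cells that parse as `NA`/empty are imputed per gene:
  0 for mutation layers, the row median otherwise, with a logged count.
* **Coordinates.** BED input and the gene annotation table are both
  0-based half-open; overlap requires ≥ 1 bp, so touching intervals do not
  overlap, and strand is ignored. 1-based annotation exports must subtract
  1 from their starts. A region overlapping no annotated gene is an error
  rather than a nearest-gene assignment — silent nearest-gene fallbacks
  change *G* in ways the user did not ask for.
* **Result files.** Numbers are written with `%.17g`, so
  `read_result_table(write_result_table(x))` reproduces `x` exactly.

## Problem sizes used in validation

The validation experiments run cohorts of 10 patients × 60 genes ×
3 modules (5 replicates) for recovery, 200 random binary matrices with
g ≤ 8 and r ≤ 5 for the k-modes oracle, 30 random 8 × 8 proximity matrices
for the k-means oracle, and 500 × 500 random interval sets for the
annotation oracle — sizes at which exhaustive enumeration is feasible, so
the implementations are checked against ground truth rather than against
themselves. At the strong effect both strategies recover planted modules
with mean adjusted Rand index well above 0.8, and recovery is monotone in
effect size on paired seeds.

## Known limitations

* Clinical variables are carried through by sample id and rendered in
  outputs, never modelled; survival or association analysis is out of
  scope.
* The gene–drug table is taken at face value (any export, e.g. from DGIdb,
  works); there is no ranking, dosage or interaction logic.
* Per-patient clustering means k is a per-cohort compromise unless
  `k = "auto"` (M1 only).
* The two strategies need |G| ≥ 4 (forest) and benefit from |G| well above
  k; single-digit gene sets are better inspected by hand.
* The static HTML report replaces interactive exploration; it is a plain
  file with colour-coded tables and external links, not a dashboard.
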