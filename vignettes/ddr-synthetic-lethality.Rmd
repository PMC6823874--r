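---
title: "Methods: DDR subtyping and synthetic-lethality discovery with ddrsl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DDR subtyping and synthetic-lethality discovery with ddrsl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ddrsl` implements a pan-cancer workflow for subtyping tumors by DNA damage
response (DDR) pathway activity and nominating synthetic-lethal (SL) drug
targets for the mutations that characterize each subtype. This vignette is
the package's own account of the statistical machinery: the models and their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the design was genuinely open.

# The analysis model

## Per-sample pathway enrichment (ssGSEA)

For one sample, genes are ranked by decreasing expression and assigned
absolute ranks $r_i = N - \mathrm{position} + 1$ (top gene gets $N$). For a
gene set $S$ the score walks the ranking, accumulating a weighted in-set
ECDF against the uniform out-of-set ECDF:

$$\mathrm{score} = \sum_{j=1}^{N}\left(
 \frac{\sum_{i \le j,\, i \in S} r_i^\alpha}{\sum_{i \in S} r_i^\alpha}
 - \frac{|\{i \le j,\, i \notin S\}|}{N - |S|}\right).$$

The score depends on expression only through ranks, so any strictly
increasing per-sample transform (log, z-scoring with positive scale,
exponentiation) leaves it bit-identical — the tests certify this, which is
why running the pipeline on z-scores rather than raw normalized values is
immaterial here. Defaults: $\alpha = 0.25$ (the conventional ssGSEA
weighting; $\alpha = 0$ weighs all in-set genes equally and gives the
antisymmetry property the tests exercise), and matrix-level normalization by
the global score range, recorded in the output's attributes.

Numerical choices: ties in expression receive average rank weights and are
walked in lexicographic gene-name order, so permuting the input gene order
never changes a score. A set that misses the universe entirely, or equals
it, leaves an ECDF undefined and is an error rather than a silent NA.

## Tumor subtyping

Samples are clustered on $d(a,b) = 1 - \rho_{\mathrm{spearman}}$ between
their pathway-score profiles ($d \in [0,2]$), with agglomerative clustering
cut at $k$ groups. The linkage is average by default — robust for
correlation distances — with complete and Ward available; $k$ defaults to 3
(the number of DDR programs the workflow is designed around) and no
automatic model selection is attempted. Merge-height ties follow the fixed
lowest-index rule of `stats::hclust`, so results are reproducible under a
fixed input ordering; cluster labels are renumbered 1..k by first
appearance. Constant profiles make the correlation undefined and raise an
error naming the offending item.

Pathway–pathway structure is summarized by Pearson correlation of enrichment
profiles (Spearman by flag) — mutually exclusive pathway programs appear as
negative blocks.

## Mutation co-occurrence and mutual exclusivity

With $S_T$ samples, $S_{1mut}$ mutated in gene 1, $S_2$ in the second
category (a cluster, or gene 2's mutants) and overlap $S_{12mut}$, the
co-occurrence p-value is the upper hypergeometric tail

$$P \;=\; \sum_{i=S_{12mut}}^{\min(S_{1mut},\,S_2)}
  \frac{\binom{S_{1mut}}{i}\binom{S_T-S_{1mut}}{S_2-i}}{\binom{S_T}{S_2}},$$

and mutual exclusivity is its complement $\mathrm{Mutex} = 1 - P$: under the
null that the two genes are mutated in the same samples, $\mathrm{Mutex} <
0.05$ rejects in favor of exclusivity. Terms are computed with `lchoose` and
combined by log-sum-exp, so cohort-scale binomial coefficients never
overflow; the complement is formed in one subtraction, making
$\mathrm{Mutex} + P = 1$ exact. The statistic is symmetric in its two
categories, which the tests verify by role swapping, and is checked against
an independent tail implementation and a 100,000-draw label-permutation
oracle.

Only non-silent mutations count as gene events; the default class set is the
standard MAF inactivating list (missense, nonsense, frameshifts, splice
site, in-frame indels, start/stop disruptions), configurable because
"non-silent" admits dialects. Genes enter the analysis if mutated in at
least 1% of samples of at least two cancer types.

Benjamini–Hochberg adjustment is applied per analysis family: all
gene-by-cluster tests jointly, and gene-pair tests per cancer type. The
family boundaries are a documented package choice — nothing in the workflow
forces one — and the cluster–gene screen keeps hits at FDR < 0.3 by default,
a deliberately permissive screen-stage threshold. Pairwise exclusivity is
computed per cancer type by default, pooled by flag.

## Four-feature SL scoring

Each candidate (primary, partner) pair is summarized by four p-values:

* `diffexp_p` — partner expression in primary-mutant vs wild-type tumors.
  Implemented as a Welch t-test on log2(CPM+1) with total-count library-size
  normalization; a negative-binomial exact test would also fit here, but the
  t-test's null calibration and planted-effect power are verified directly
  by simulation, which is the property the pipeline actually relies on.
* `corr_p` (with `corr_r`) — Pearson correlation of the two genes'
  expression, $t$-transform with $n-2$ df.
* `mutex_p` — the mutual-exclusivity statistic above, shared implementation.
* `sharedpath_p` — upper hypergeometric tail on pathway-membership overlap
  (N pathways, K containing gene 1, n containing gene 2, k containing both);
  zero shared pathways gives p = 1.

Features are raw p-values (no −log10 transform), assembled per cancer type
by default with pooling available; strata with fewer than two samples on
either side of the mutation split are skipped with a warning rather than
producing unstable statistics.

A Random Forest (500 trees, √p features per split, fixed seed recorded in a
model fingerprint) maps the four features to an SL probability. Honest
performance summaries come from out-of-bag votes (`oob_auroc`) or stratified
5-fold cross-validation (`sl_cv_auroc`); training labels are user-supplied —
in the synthetic workflow, the planted-pair ground truth.

## The validation cascade

* **Conditional essentiality**: one-sided Welch t-test that the partner's
  RNAi essentiality score is *lower* (more essential) in primary-mutant cell
  lines; default α = 0.05.
* **Survival benefit**: within primary-mutated tumors, split at the median
  of partner expression; samples exactly at the median go to the "down" arm
  (the boundary rule must be fixed somewhere — ours is ≤, documented and
  tested). Log-rank test plus a direction call from restricted mean
  disease-free survival; benefit means the down arm progresses later.
  Default α = 0.05, minimum 5 samples per arm; the median is computed within
  the mutated stratum by default (the comparison is conditioned on the
  mutation, so the split should be too), cohort-wide by option.
* **Drug sensitivity**: one-sided Welch t-test that mutant lines have lower
  LN-IC50 for drugs targeting the partner; α = 0.1. This annotates
  candidate therapies but does not gate the final list.

The final list requires essentiality AND survival, each in its beneficial
direction. All four tests hold their null size — rejection rates at α = 0.05
stay within [0.03, 0.07] over 1,000 null replicates in the test suite.

## Network

Validated pairs become typed edges: `sl_interaction` (weight = RF
probability), `mutated_in` (primary gene to cancer type, when the record
carries one), `drug_targets`, and `drug_sensitive` (weight = one-sided p). A
drug node requires both a target link to an included partner and a
sensitivity flag against a connected primary — the conjunction is the
default, an either-or mode exists. Relaxing any validation threshold can
only add edges (monotonicity, tested). Serialization is a single edge-list
TSV with endpoint types inlined, round-tripping through `read_network()`.

# The synthetic cohort

`generate_cohort()` draws, per sample: a latent cluster (uniform), a cancer
type, negative-binomial expression counts (baseline mean 100, dispersion
0.2, so variance = μ + 0.2μ²), Bernoulli mutations, and exponential
disease-free survival with uniform censoring. Planted structure:

* **Cluster enrichment** — the 10 DDR pathways are split disjointly across
  the 3 clusters; genes of a cluster's pathways get a 3-fold mean shift in
  that cluster. Z-scores are computed per gene across samples from
  log2(count+1).
* **Cluster-exclusive mutations** — 5 signature genes per cluster mutate at
  0.3 in-cluster vs 0.02 baseline, which induces mutual exclusivity across
  clusters without any rejection sampling.
* **SL pairs** — each planted pair couples a signature gene (primary) to a
  dedicated partner: the partner's mean drops 4-fold in primary mutants
  (diffexp), both genes share a log-normal latent factor of scale 0.6
  (correlation), the partner mutates at 0.15 in primary wild-types and not
  at all in primary mutants (exclusivity; the complete-exclusivity default
  is the textbook SL pattern, partial strength configurable), and both genes
  are co-inserted into 3 background pathways (shared pathway).
* **Survival** — baseline hazard 0.02/month; samples that are
  co-inactivated (primary mutated AND partner expression at or below the
  partner's median *within the mutated stratum*) have their hazard divided
  by `sl_survival_hr` (default 3), i.e. the hazard ratio is expressed as
  comparison-arm over co-inactivated arm, matching the benefit direction the
  cascade tests. The stratum-relative median matters: the diffexp channel
  pushes most mutants below the cohort-wide partner median, so a cohort-wide
  definition would hand the protective effect to nearly the whole stratum
  and leave the within-stratum split with nothing to detect.
* **Screens** — cell lines mutate primaries at rate 0.5; partner RNAi
  scores shift by −2 (sd 1) in mutant lines; one drug per partner shifts
  LN-IC50 by −2 in mutant lines; decoy drugs carry no shift.

Everything is a deterministic function of `seed` (the screen generator
offsets the seed to keep its stream independent of the cohort draw), and two
runs with one config are byte-identical through the full pipeline.

## Benchmark scales

Problem sizes in the test suite are chosen to exercise each property at the
smallest scale where it is statistically unambiguous:

* Cluster recovery: 3 cancer types × 100 samples (n = 300), ARI ≥ 0.9
  against planted labels at a fixed seed.
* Mutation-structure recovery: one cancer type, n = 500, in-cluster rate
  0.3 vs baseline 0.02, 20 seeded replicates.
* RF ranking: 20 planted pairs among 400 candidates (n = 300), pooled
  features, cross-validated AUROC ≥ 0.9 with a label-permutation chance
  control.
* Validation cascade and network: an exemplar-scale configuration — 3
  planted pairs, 200 samples per type (n = 600), hazard ratio 6, baseline
  hazard 0.04/month — sized by an a-priori power calculation so each pair's
  log-rank filter exceeds 99% power (≈ 34 samples per arm, ≈ 30 events).
  The KM channel saturates when many planted pairs share cluster-correlated
  primaries: protective hazard effects compound across overlapping
  co-inactivation masks and censoring then removes the per-pair contrast.
  Biologically, a cohort where every tumor is co-inactivated for several SL
  pairs is not the situation the validation step addresses; the exemplar
  scale — a handful of strong pairs — is.

## What passing tests do and do not show

The generator produces idealized data: independent samples, a single global
library size, no batch effects, no tumor purity or copy-number confounding,
mutation probabilities homogeneous within cluster, exponential survival with
uniform censoring, and effect channels that are conditionally independent
given the planted structure. Passing the planted-recovery tests shows that
the statistics detect the signals they were designed for at realistic effect
sizes and that the machinery is numerically correct against independent
oracles. It does not show that real tumor cohorts satisfy these assumptions
— in real data, mutation-burden heterogeneity alone can mimic exclusivity,
expression correlation is dominated by lineage, and survival effects are
confounded by stage and treatment. The package deliberately leaves
covariate-adjusted exclusivity and multivariate survival out of scope.

# Known limitations

* The hypergeometric exclusivity test conditions on margins and ignores
  per-sample mutation rates; highly mutated samples inflate co-occurrence.
* The differential-expression feature is a two-group location test on
  transformed counts, not a count-model test; with very low counts or
  extreme dispersion its calibration degrades (the simulated regime,
  μ = 100, dispersion 0.2, is comfortable).
* The RF is trained on whatever labels are supplied; with literature-derived
  positives its probabilities inherit literature bias.
* Survival validation uses a median split and log-rank only — no hazard
  modeling, no covariates, no FDR across validated pairs (deliberate: the
  cascade is a filter, not an inference report).
* k for the subtyping is a parameter, not inferred; the workflow's
  default of 3 reflects the DDR-program structure it targets.
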