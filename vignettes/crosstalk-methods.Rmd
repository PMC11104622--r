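---
title: "Discovering disease-associated ligand-receptor crosstalk with paired single-cell and spatial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering disease-associated ligand-receptor crosstalk with paired single-cell and spatial data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcrosstalk)
```

## The problem

Single-cell RNA-seq can propose ligand-receptor (L-R) channels between
annotated cell types, but it dissociates the tissue: two cell types that
"communicate" in the inference may never sit near each other. Spatial
transcriptomics keeps the geometry but mixes several cells per capture
spot (a 55 µm Visium spot holds roughly 8-15 cells), so it cannot
attribute a transcript to a cell type on its own. `lrcrosstalk`
implements an integrative filter chain that uses each modality to
discipline the other:

1. **Communication inference** (single-cell side): per condition, score
   every (source type, target type, L-R pair) and keep interactions
   significant under a label-permutation null (p < 0.05).
2. **Spatial plausibility** (spatial side): deconvolve spots into
   cell-type abundances, cluster spots by composition, and keep only
   interactions whose source and target types *positively co-occur* in
   the selected compositional clusters. Self-pairs (autocrine signaling)
   bypass this filter.
3. **Differential regulation**: between two conditions, keep pairs whose
   ligand and receptor both change with |lnFC| ≥ 0.1, BH-adjusted
   p < 0.05, and the *same sign* (a channel is up- or down-regulated as a
   unit, not half of one).
4. **Spatial co-expression**: surviving pairs are mapped back onto the
   slides with the minimum-principle score; failure there (for example a
   gene missing from an FFPE probe panel) flags a hit rather than
   deleting it, because a probe gap is a finding about the assay, not the
   biology.

Because the cohort datasets such analyses run on are controlled-access,
the package carries a first-class synthetic generator whose ground truth
(planted programs, spot compositions, co-localization structure) makes
every stage testable at desk scale.

## The models, stage by stage

### Quality control

A unit (cell or spot) is kept iff all four hold: total counts ≥ 500,
expressed genes ≥ 250, mitochondrial percentage < 20 (strict, by the
`MT-` prefix), and log10(genes)/log10(counts) ≥ 0.80. The ratio is read
as a quotient of logs: the alternative reading log10(genes/counts) is
≤ 0 whenever genes ≤ counts and could never reach 0.80, so it is not a
viable interpretation. Units with ≤ 1 counts are removed by the count
filter and never reach the (undefined) ratio. On small synthetic panels
the gene-count and ratio thresholds are rescaled (e.g. 50 genes, ratio
0.4 on a 200-gene panel); with 200 genes a unit simply cannot express
250, and log10(genes) saturates near 2.3 while log10(counts) keeps
growing, so the clinical defaults would empty the panel for arithmetic
reasons.

### Normalization

Counts are scaled per unit to a common total of 10,000 and transformed
with natural `log1p` — the de-facto default of the single-cell toolkits
this pipeline interoperates with. Zeros stay zero, so sparsity is
preserved.

### Communication scoring

The scoring follows the documented defaults of the standard
communication-inference toolkit:

* group expression of a gene in a cell type is **Tukey's trimean**
  (Q1 + 2·Q2 + Q3)/4 with quartiles by linear interpolation — a robust
  location summary that is 0 unless more than half the cells express the
  gene;
* a multi-subunit receptor's level is the **geometric mean** of its
  subunit levels, and 0 if any subunit is absent (a complex missing a
  subunit cannot signal);
* the interaction score is the bounded Hill mass-action term
  L·R/(Kh + L·R) with Kh = 0.5, monotone in both levels and < 1;
* significance comes from shuffling cell-type labels within the
  condition (default 100 permutations) with the add-one estimator
  p = (#{permuted ≥ observed} + 1)/(B + 1), so p ∈ (0, 1] and the
  smallest reachable p is 1/(B+1).

### Differential L-R analysis

For each candidate interaction the ligand is tested in its source type
and every receptor subunit in its target type: two-sided Wilcoxon
rank-sum between the two conditions on normalized expression, with
lnFC = ln(mean(expm1(B)) + ε) − ln(mean(expm1(A)) + ε), ε = 1e-9. The
estimator de-logs before averaging so the fold change lives on the
expression scale, and ε only guards genes silent in a whole group.
P-values are BH-adjusted within each cell type (the scope in which the
family of tests is exchangeable). The second-named condition is the
numerator, so positive lnFC means "up in disease" for a Healthy-first
comparison. Complexes require every subunit to pass at the same sign;
the complex lnFC is the subunit mean and the complex adjusted p the
subunit maximum.

### Deconvolution

The spot × cell-type abundance matrix is estimated by regularized
nonnegative least squares: per spot, minimize
‖y − S·a‖² + λ‖a − ā‖² with a ≥ 0, where S holds per-type mean relative
expression profiles on the gene intersection of the two panels (columns
sum to 1), y is the spot's counts scaled to 8 cells' worth of signal,
and ā is the uniform prior summing to 8 (the expected cells per spot).
This replaces a full Bayesian deconvolution deliberately: it is
deterministic, exact on noiseless mixtures, solved to stationarity by
projected coordinate descent (strictly convex for λ > 0; iteration cap
10,000, tolerance 1e-8), and sufficient for what downstream stages
consume — compositional clusters and presence/absence calls. The
detection-sensitivity convention α = 20 maps to the *relative* ridge
weight 1/α; the effective λ is (1/α)·mean(diag(SᵀS)) so that the prior's
pull is invariant to panel size. An unscaled 1/20 would dominate the
data term on small panels and flatten every spot toward the uniform
prior, which is fatal for presence calls; this scaling is a convention
of this package, not a claim about the original Bayesian model.

Because every cell type shares a common baseline expression program, the
full-panel signatures are collinear, and residual noise tends to be
attributed to several absent types at once — correlated "bleed" that can
fabricate co-occurrence between types that are never truly present.
`build_signatures(marker_genes_per_type = )` restricts the signature to
the most discriminative genes per type; the spatial analyses in this
package use 10 markers per type, while the default keeps all shared
genes.

### Compositional clustering and co-occurrence

k-means runs on row-proportion abundances for k = 1..15 with 10 random
restarts plus a warm start that augments the previous k's centers with
the worst-fitted spot — which guarantees WSS(k+1) ≤ WSS(k). The elbow is
chosen algorithmically: both axes are rescaled to the unit square and
the selected k maximizes the distance to the chord between the first and
last points. The original workflow selects k visually; `set_selected_k()`
preserves that override. Cluster selection ranks clusters by (fraction
of spots from diseased conditions) × (mean summed proportion of the cell
types of interest), ties to the lower id, with a manual override.

Within a selected cluster, a type is *present* in a spot when its
proportion exceeds 0.05 (the threshold is not dictated by the underlying
method and is exposed in the config). For each unordered pair the exact
hypergeometric tails P[X ≥ j] and P[X ≤ j] — with N spots, marginal
presence counts N1, N2 and observed co-presence j — classify the pair as
positive (p_gt < 0.05), negative (p_lt < 0.05) or random. No correction
across pairs is applied, matching the underlying co-occurrence
framework; α is configurable. Two structural notes:

* saturated marginals carry no signal (N1 = N2 = N forces j = N and
  p_gt = 1), so a co-occurrence design in which both members of a pair
  dominate a whole neighbourhood is *undetectable by construction*;
* self-pairs are classified positive by fiat: autocrine signaling is
  real and must not be blocked by a presence/absence argument.

Classifications from several selected clusters combine by union
(default) or intersection.

### Minimum-principle co-expression and spatial correlation

A spot's co-expression of a gene set is the minimum of the genes'
normalized expression there; scores below the noise threshold t (default
0) are reported as 0, and for two-gene sets each spot gets a channel
(none / gene1-only / gene2-only / co-expressed, with presence meaning
strictly above t). A gene absent from the spot panel raises an error
naming it — downstream, `build_hits()` converts that error into an
evidence flag on the hit. Validation against markers uses per-slide
Pearson correlation, aggregated by the median across slides (robust to
slide-count imbalance between conditions), overall and per condition.

## The synthetic generator

`simulation_config()` defaults encode the study conditions the pipeline
is built for: three conditions (Healthy, AKI, CKD), an average of 8
cells per spot (zero-truncated Poisson), negative-binomial counts with a
single shared dispersion of 2 (simplest overdispersed count model),
log-normal library sizes with mean 2500, 10 markers per type at 15-fold
enrichment, and Dirichlet spot compositions organized into contiguous
neighbourhood archetypes (base concentration 0.15, dominant 6). Planted
condition effects use |lnFC| magnitudes in the 0.1-1.1 range reported
for real disease-modulated channels, with 0.5 as the default working
effect size.

Design choices worth knowing:

* **Colocalization is a niche, not a saturation.** A colocalized pair
  shares a host archetype in which half the spots (the niche) have both
  members' concentration boosted by 2.5 and the rest neither — their
  presence then *co-varies* across the host cluster's spots, which is
  the only regime in which the hypergeometric test can see them (see the
  saturation note above). Segregated pairs dominate disjoint archetypes
  and never co-dominate one.
* **Planted channels exist at baseline.** A planted pair's ligand is
  elevated 3-fold in its source type and its receptor in its target type
  across *all* conditions, with the condition effect multiplying on top.
  A down-regulated channel that never existed in the healthy state would
  be invisible to any per-condition significance screen — you cannot
  lose what you never had.
* **Spot counts are sums of latent single-cell draws**, matching the
  deconvolution model's assumption and the physical capture process,
  rather than draws around mixed means.
* **A "fully null" simulation means exchangeable labels.** For the
  permutation-calibration check the generator must set
  `type_jitter_sdlog = 0` *and* `marker_fold = 1`: with marker programs
  present, cell-type labels genuinely predict normalized L-R levels
  (markers shift each cell's library composition), the null hypothesis
  is false, and rejection rates above α are correct behaviour, not
  miscalibration.

What the generator does not emulate: batch effects, doublets, spatial
autocorrelation beyond the archetype blocks, probe dropout, and
cell-type abundance differences between conditions. Tests passing on
this generator therefore show that the machinery is correct and
calibrated under its stated model — not that real cohort data meet that
model.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use 5 cell types, panels of
120-250 genes, 100-300 cells per type and condition, 100-150 spots per
sample and 2 samples per condition — sizes at which every stage's
behaviour (recovery, calibration, determinism) is measurable in seconds
per replicate while leaving comfortable statistical margins. Key
numerical conventions: quartiles use R's default linear interpolation
(type 7); the NNLS solver stops when the largest coordinate update falls
below 1e-8; k-means ties and restarts are fixed by the recorded seed;
TSV output carries 6 significant digits; and all randomness in a
pipeline run derives from the single config seed, which makes full runs
byte-reproducible.

## Limitations

* The deconvolution stand-in shares only inputs and outputs with the
  Bayesian model it replaces; its abundance *values* are not comparable
  across technologies, only its proportions and presence calls are used.
* The co-occurrence test is marginal per pair; with many cell types the
  positive classifications carry the usual multiplicity caveat.
* lnFC on de-logged means is sensitive to a handful of extreme cells in
  small groups; the Wilcoxon p-value, not the fold change, carries the
  inferential weight.
* The elbow rule is a heuristic; when the WSS curve is nearly straight
  its argmax is weakly determined, and the manual override is the right
  tool.
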