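# lrcrosstalk

Discovery of disease-associated ligand–receptor (L-R) interactions by
integrating single-cell RNA-seq communication inference with spatial
transcriptomics validation.

## Who this is for, and what it does

Single-cell data can propose that cell type A signals to cell type B
through a ligand–receptor pair, but it cannot show that A and B ever sit
near each other in the tissue; spatial transcriptomics keeps the
geometry but mixes ~8–15 cells per capture spot. `lrcrosstalk` chains
the two modalities into one discovery pipeline for researchers studying
how cell–cell communication changes along a disease course (e.g.
healthy → acute injury → chronic disease):

1. **Communication scoring** per condition: group expression by Tukey's
   trimean, receptor complexes by zero-annihilating geometric mean,
   interaction intensity by the Hill mass-action score
   `L·R/(Kh + L·R)` (Kh = 0.5), significance by a cell-type
   label-permutation null, `p = (#{perm ≥ obs} + 1)/(B + 1)`.
2. **Differential L-R analysis** between conditions: per-gene Wilcoxon
   tests, `lnFC = ln(mean(expm1(B)) + ε) − ln(mean(expm1(A)) + ε)`,
   Benjamini–Hochberg adjustment per cell type; keep pairs with
   `|lnFC| ≥ 0.1`, `padj < 0.05` for ligand *and* every receptor
   subunit, all with the same sign.
3. **Spot deconvolution**: regularized nonnegative least squares of spot
   counts against cell-type signatures on the shared gene set
   (expected 8 cells per spot; detection-sensitivity convention α = 20
   maps to a relative ridge weight 1/α).
4. **Compositional clustering + co-occurrence**: k-means on spot
   proportions with elbow selection over k = 1..15; within selected
   clusters, exact hypergeometric tails
   `P[X ≥ j]`, `P[X ≤ j]` classify each cell-type pair as
   positive / negative / random co-occurrence.
5. **The filter chain**: keep differential interactions whose source and
   target positively co-occur (autocrine self-pairs always pass), then
   map survivors onto the slides with the minimum-principle
   co-expression score (a spot co-expresses a gene set at the level of
   its weakest member); genes missing from the spot panel become
   evidence flags, not exclusions.

A first-class synthetic generator produces paired datasets with known
ground truth — planted condition-dependent L-R programs, Dirichlet spot
compositions in spatial neighbourhood archetypes, colocalized and
segregated cell-type pairs — so the whole chain is testable without
controlled-access cohort data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R           # paired dataset, 6 planted programs
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_communication.R
Rscript analysis/04_deconvolve_compose.R
Rscript analysis/05_integrate.R
Rscript analysis/06_recovery_report.R
```

Stage 3 prints the differential L-R summary over the three pairwise
comparisons of the simulated Healthy/AKI/CKD design:

```
     comparison n_up n_down
 Healthy vs AKI    1      0
 Healthy vs CKD    3      1
     AKI vs CKD    3      2
```

Stage 4 clusters the deconvolved spots (the elbow selects k = 3 on this
dataset), selects the two clusters richest in diseased spots and in the
cell types of interest, and finds exactly the planted colocalized pair
positively co-occurring:

```
elbow-selected k: 3
selected compositional clusters: 3 1
positively co-occurring type pairs in selected clusters:
 cluster_id type_a type_b
          3     T1     T2
```

Stage 6 scores the run against the generator's ground truth:

```
                       metric value
             planted_programs     6
     recovered_with_direction     4
               unplanted_hits     0
 segregated_planted_recovered     0
```

Six programs were planted; the four between colocalized or identical
cell types are all recovered with the correct direction and no false
hits, and the two planted between *segregated* types are absent —
removed by the co-occurrence filter exactly as the design intends.

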