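---
title: "Methods: late-phase asthma biomarkers, from panel discovery to drug matching"
author: "larconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: late-phase asthma biomarkers, from panel discovery to drug matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`larconnect` implements a four-stage transcriptomic analysis pipeline for the
allergen-induced late-phase asthmatic response (LAR):

1. **Panel discovery** — spirometry-based dual-responder classification and
   sparse PLS-DA selection of a blood mRNA biomarker panel in an allergen
   challenge cohort.
2. **Multi-cohort evaluation** — repeated cross-validated classification of
   asthma exacerbation and severity with PLS-DA and random forests, stratified
   by sex, with percentage-rank importance aggregation.
3. **Cell-type resolution** — pseudobulk differential expression of the
   biomarkers in single-cell biopsy data before and after allergen challenge.
4. **Drug-signature matching** — connectivity scoring of a PBMC compound
   screen to find drugs that reverse the cell-specific biomarker response.

Every stage operates on synthetic data emitted by seeded generators with
planted ground truth, so the whole pipeline is testable without any external
download. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic conditions do and do not establish
about real data.

# Stage 0: spirometry and responder classes

After allergen inhalation, FEV1 is followed for 7 hours. All challenge
subjects show an early-phase fall of at least 20% within 0–2 h. A subject is
a **dual responder (DR)** if the maximum FEV1 fall in the closed late-phase
window [3, 7] h is at least 15% (`max_late_drop <= -15`); the window boundary
at exactly 3 h or 7 h counts, and a fall of exactly 15% is inclusive — the
threshold's openness is not printed anywhere we know of, and we chose the
inclusive reading. A borderline subject (fall between 10 and 15% at 7 h) is
rescued to DR when the **allergen-induced shift** — PC20(pre) / PC20(post),
the fold-increase in methacholine hyperresponsiveness — is at least 2,
capturing late responses still developing at the last measurement. The 7 h
fall is taken from the measurement nearest 7 h within ±15 minutes.
Everyone else is an isolated early responder (ER).

`classify_responder()` applies exactly this rule set and reports which rule
fired, and the generator plants two borderline DRs per 20 (configurable) so
the rescue path is always exercised.

# Stage 1a: sparse PLS-DA panel discovery

## Model

For a samples × genes matrix \(X\) (columns centred and unit-scaled) and a
two-class factor dummy-coded into a centred \(Y\), each component \(h\)
solves the PLS problem via the dominant left singular vector \(w\) of
\(X_h^\top Y\). Sparsity is imposed by **magnitude-ranked soft-thresholding**:
with budget `keepX[h]`, the threshold is the (keepX+1)-th largest \(|w_j|\);
surviving entries are shrunk by it, all others set to zero, and \(w\) is
renormalised to unit length — so exactly `keepX[h]` weights are nonzero.
Scores are \(t = X_h w\); \(X\) is deflated by \(t p^\top\)
(\(p = X_h^\top t / t^\top t\)); \(Y\) is not deflated. Two components are
the default throughout. The sign of each \(w\) is fixed by making its
largest-magnitude entry positive, which makes fits order-independent.

Prediction applies the stored scaling, projects through
\(W^* = W (P^\top W)^{-1}\), and returns the regression prediction for the
positive-class dummy column; a sample at the training mean scores exactly 0.
For two classes this is monotone-equivalent to the maximum-distance class
rule. Variable importance uses the standard VIP,
\(\mathrm{VIP}_j = \sqrt{p \sum_h SS_h w_{jh}^2 / \sum_h SS_h}\) with
\(SS_h = (t_h^\top t_h)\sum_k q_{kh}^2\); the mean of \(\mathrm{VIP}^2\) over
genes is identically 1.

## Tuning and selection

`repeated_cv_auc()` evaluates a keepX grid (default 5, 10, 15, 20, 25, 30
transcripts per component) by stratified 5-fold cross-validation repeated 20
times. Per repeat, test folds are scored by models fit on the remaining
folds and the AUC is computed from the repeat's **pooled test scores**; the
table reports mean ± SD over repeats. Pooling within a repeat (rather than
averaging per-fold AUCs) was an open choice; pooled scores are less noisy at
these sample sizes (7 test samples per fold). Repeat \(r\) derives its fold
assignment from `seed + r`, so any single repeat can be reproduced without
rerunning the rest.

`select_panel()` retains the configuration with the **fewest transcripts
among those with mean AUC above 0.70**; ties break toward higher mean AUC,
then lower SD (tie-breaking beyond parsimony is not printed in the source
material; this ordering is our choice). If nothing qualifies the result is
an explicit "no panel", not an error. AUC itself is computed by the
mid-rank Mann–Whitney formula and is verified in the tests against an
all-pairs brute-force oracle.

## Preprocessing conventions

* `log2_clip()` log2-transforms and **then** replaces negative results and
  missing values with zero (the order is ambiguous in prose descriptions of
  this rule; transform-first matches "log2-transformed and values below 0
  replaced").
* `log_cpm()` uses `log2((count + prior) / (libsize + 2 prior) * 1e6)` with
  prior 0.5 — the edgeR-style denominator, chosen so that a zero prior gives
  exact invariance to per-sample count scaling.
* `filter_low_abundance()` removes housekeeping genes and genes whose mean
  count is at most `mean + 2 SD` of the negative-control counts. The exact
  NanoString filter behind the published "600 of 770 retained" outcome is
  unstated; mean + 2 SD of negative controls is the platform convention. The
  generator's fraction of near-background genes (0.17) was set once so the
  default cohort lands near that outcome (~600 retained).
* Probe-level arrays are collapsed by within-sample means over probes sharing
  a symbol; transcript-level counts are summed (and summing is refused on the
  log scale, where it is meaningless). Gene identifiers match
  case-sensitively after whitespace trimming.

# Stage 1b: multi-cohort evaluation

`enumerate_grid()` builds the full Cartesian model grid — e.g. 6 panels × 4
comparisons × 3 sex strata × 2 classifiers = 144 exacerbation models, and 4
sample types × 3 comparisons × 6 panels × 3 strata × 2 classifiers = 432
severity models. `evaluate_cell()` runs one cell: subset samples to the
comparison and stratum, drop panel genes absent from the dataset (an error
if more than half are missing), then 20×5-fold stratified CV with either

* **PLS-DA**: the dense (keepX = p) two-component model above, or
* **random forest**: a 500-tree `ranger` ensemble, `sqrt(p)` features per
  split, impurity (node-purity) importance, seeded. The forest is
  deliberately backed by an existing implementation — the evaluation
  harness, not the tree ensemble, is the contribution here.

Importance scores come from a refit on the full cell data (VIP or node
purity); whether the source analysis refit or averaged fold importances is
unstated, and full-data refit is the choice. `percentage_rank()` maps each
model's importances to [0, 1] (top feature 1, bottom 0, ties averaged), and
`aggregate_ranks()` averages each biomarker's rank across models with mean
AUC > 0.70, counting only models whose panel contains the biomarker.

The "combined" sex stratum uses observed sex where available and imputed sex
otherwise. `impute_sex()` performs PCA on the centred Y-chromosome gene
submatrix and k-means (k = 2, 10 seeded restarts) on PC1–PC2, labelling the
cluster with higher mean Y expression male. With the generator's planted
5-SD Y-gene separation the imputation is exact; real datasets with partial
RNA degradation will do worse — the synthetic test establishes correctness
of the procedure, not its field accuracy.

## Batch correction

`combat_adjust()` is an in-package implementation of the parametric
empirical-Bayes location/scale batch adjustment: per-gene standardisation
with batch (and optionally the biological group, protecting it) in the
design; per-batch gene-wise location effects shrunk toward a normal prior
and scale effects toward an inverse-gamma prior, both fit across genes by
the method of moments and solved by the standard iterative posterior
update; back-transformation. Two conventions matter numerically:

* all variances are maximum-likelihood (1/n), so the standardised
  within-batch variance of duplicated batches is exactly 1 and **two
  identical batches pass through unchanged** to floating-point precision;
* degenerate priors (zero across-gene variance of the estimated effects)
  disable shrinkage for that batch rather than dividing by zero.

Empirical-Bayes shrinkage means planted batch shifts are removed *almost*
but not exactly: the residual per-gene batch-mean gap is of order
\((\hat\gamma - \bar\gamma)\, s^2/(n\tau^2 + s^2)\) — a few percent of the
planted shift under realistic noise (the tests assert at least 95%
removal). Exact removal is only approached as within-batch noise vanishes;
this is a property of the method, not of the implementation, and the
implementation agrees with `sva::ComBat` to correlation > 0.999 on
non-degenerate fixtures. Genes constant across all samples have their pooled
variance floored with a warning.

# Stage 2: pseudobulk differential expression

Single-cell counts are normalised per cell,
\(\log_2(\mathrm{count}/\mathrm{libsize} \times s + 1)\), with \(s\) the
median library size by default (a fixed \(10^4\) is available); sparse zeros
stay zero. `pseudobulk_mean()` averages logcounts over every (cell type,
sample) stratum, dropping strata under 10 cells (configurable; the threshold
is our choice). Per cell type, `moderated_fit()` fits gene-wise least
squares for the allergen-vs-baseline contrast and shrinks residual variances
with `limma::squeezeVar` (mean–variance trend on): the posterior variance is
\(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\) on \(d_0 + d\) degrees of
freedom (capped at the pooled residual df, as in limma). Forcing \(d_0 = 0\)
recovers the ordinary t, \(d_0 = \infty\) the complete-pooling t; the
moderated t interpolates between them, and the tests verify agreement with
`limma::eBayes` to machine precision.

Results are **restricted to the biomarker list first and BH-adjusted within
each cell type**, flagging significance at FDR < 20%. Whether restriction
precedes adjustment is ambiguous in the source description; restriction-first
is the choice here, and it is the more conservative reading for per-cell-type
counts of significant biomarkers. The contrast is unpaired (condition as a
fixed effect, subject not modelled), mirroring the pseudobulk design; at 4
subjects per group a paired model would spend half the residual df.

The biopsy generator plants cell-type-restricted up-regulation (mean × 2^effect
in asthma-group allergen-condition cells of designated cell types only), so
sensitivity in the target cell type and the null flag rate in controls are
directly measurable. With effect 1.5 and 30 cells per stratum, sensitivity
is ≥ 80% at ≤ 25% null flagging; this certifies the machinery, not any
specific biological count, which depends on data we do not ship.

# Stage 3: drug connectivity

`build_drug_signatures()` pseudobulks a perturbation screen per (cell type,
compound, donor), then per cell type fits one moderated model per gene with
a compound-indicator design, vehicle (DMSO) as reference: coefficients are
log2 fold changes vs vehicle with moderated p-values. Donor or plate is not
included in the compound regression (the source design is unstated;
compound-only is the default and donor-blocking is a one-line design change).
Genes are ranked by the **ranking score** \(s = \log_2\mathrm{FC} \times
(-\log_{10} p)\).

The **enrichment score** of a gene set along a compound's ranked list is the
GSEA-style weighted Kolmogorov–Smirnov running sum: genes sorted by \(s\)
descending (ties by stable gene id), hits advance the sum by
\(|s|^\alpha / \sum_{set} |s|^\alpha\) (\(\alpha = 1\)), misses retreat by
\(1/(N-m)\); the ES is the extreme running-sum value. The source material
names no formula for its enrichment score; the weighted KS statistic is the
field-standard reading, and the implementation matches a brute-force
\(O(Nm)\) oracle exactly on all tested instances. The **connectivity
score** is \(CS = ES_{up} - ES_{down}\): negative when a drug moves the
disease up-set down and the down-set up (a *reverser*), positive for a
*mimic*.

Raw KS enrichment is bounded, \(|CS| \le 2\), yet connectivity magnitudes
above 3 are meaningful in the published analysis — so the reported scale
cannot be raw ES. `normalized_es()` therefore divides the ES by the mean
|ES| of same-size random sets with matching sign (seeded permutations,
default 1000), and reporting at \(|CS| > 3\) uses these normalised scores.
Reverser *ranking* (the recovery criterion) uses raw ES — it is
permutation-free and monotone-equivalent for fixed set sizes. Positive
controls are scored but excluded from reverser/mimic ranking by default.

The screen generator plants one reverser and one mimic among 144 compounds
(plus 2 positive-control analogues and DMSO, 3 donors, 5 cell types);
remaining compounds perturb a few random non-target genes. Across 20 seeded
screens the planted reverser is the most negative mean-CS compound in at
least 18 (in practice all 20 at effect 1.5 with 4 cells per stratum).

# Over-representation analysis

`ora()` is a one-sided Fisher exact (hypergeometric tail) test of a gene
list against each set of a GMT library within a stated universe, BH-adjusted
across the library, significant at FDR < 1% by default. The universe
defaults to all genes of the analysed platform after filtering — web
enrichment services use their own backgrounds, which is one reason published
set counts are not reproducible offline and are out of scope.
`frequent_genes()` tallies list genes across significant sets.

# Synthetic data: what it establishes

The generators emit negative-binomial counts (dispersion size 10 for bulk
NanoString-like data, 2 for single cell — conventional overdispersion
levels), Gaussian log-intensities for array-like cohorts, FEV1/PC20
trajectories consistent with the planted responder classes, Y-gene elevation
for sex, additive batch shifts, and planted effects expressed in
standardized (log2) units via a delta-method conversion to mean fold
changes. All generators are deterministic under a fixed seed and return the
planted truth alongside the data.

The five-panel fixture reproduces the published slot arithmetic — sizes
40/33/35/34/14, 156 slots, 109 unique symbols — and every printed overlap
marginal that can be satisfied jointly (37 + 3 split of the first panel, 10
Trinity-unique genes, 11 three-way-shared genes, 9 genes shared by the
isoform and Ensembl panels only). The printed overlap description is not
jointly satisfiable in full: the isoform panel would need at least 35 slots
but has 33, so the remaining Venn cells are the fixture's own.

Synthetic data has no gene–gene correlation structure, no doublets or
ambient RNA, and planted effects are homogeneous across genes of a set.
Passing tests therefore certify the *statistical machinery* — recovery of
planted truth under known conditions, exact agreement with brute-force
oracles, determinism — and not performance on real cohorts, where published
headline numbers (73 ± 6% challenge AUC, 15/144 and 103/432 qualifying
models, 55/42 up-regulated biomarkers in CD8/CD4 T cells, 72% sex-imputation
accuracy, the specific drug identities) depend on datasets not shipped here.

# Problem sizes and determinism

Default test and demonstration sizes: 35-subject challenge cohort with 770 +
8 control genes; bulk cohorts of 60–100 samples per dataset (the full-size
designs of the source cohorts are available via `default_bulk_design()`);
biopsy data with 2 groups × 4 subjects × 2 conditions × 5 cell types × 30
cells; screens of 144 compounds × 3 donors × 5 cell types at 4–8 cells per
condition. These sizes were chosen so the full suite and the acceptance
script each complete in minutes on a single core while every recovery
criterion remains well-powered. All stochastic stages take explicit seeds;
the pipeline runner derives per-stage seeds from one global seed at fixed
offsets so stages are independently reproducible, and manifests record md5
checksums of every output.
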