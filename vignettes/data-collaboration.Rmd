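---
title: "Data collaboration analysis for small-sample diabetes prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data collaboration analysis for small-sample diabetes prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A municipality screens its citizens once a year; a university hospital
records many visits per patient. Both hold the same fifteen routine
measurements — demographics, glycaemia markers (HbA1c, fasting and casual
glucose), a red-cell panel, lipids, liver enzymes, creatinine, and
semi-quantitative urinalysis — and both would like a model that predicts
incident diabetes three years ahead. Neither may share patient-level
records. `dcollab` implements **data collaboration (DC) analysis** for this
setting: each institution (*worker*) transmits only a dimension-reduced
*intermediate representation* of its data, and a coordinating *master*
stitches the representations into one trainable dataset without ever seeing
a raw record.

## The collaboration algorithm

Worker $i$ holds $X_i \in \mathbb{R}^{m_i \times d}$ over the $d$ common
encoded features and picks a private linear compression $f_i$ with target
dimension $l_i < d$ (PCA by default):

$$\tilde{X}_i = f_i(X_i) \in \mathbb{R}^{m_i \times l_i}.$$

Because each worker chooses its own $f_i$, the $\tilde{X}_i$ live in
incompatible coordinate systems. The bridge is an artificial **anchor
matrix** $X^{\mathrm{anc}} \in \mathbb{R}^{r \times d}$, shared identically
by all workers — by default a uniform random matrix over public
per-feature reference intervals, so it reveals nothing about any cohort.
Each worker also transmits its anchor image
$\tilde{X}_i^{\mathrm{anc}} = f_i(X^{\mathrm{anc}})$.

The master chooses a common target $Z \in \mathbb{R}^{r \times k}$ — the
top-$k$ left singular vectors of the concatenation
$[\tilde{X}_1^{\mathrm{anc}} \mid \cdots \mid \tilde{X}_n^{\mathrm{anc}}]$
— and solves one least-squares problem per worker,

$$G_i = \arg\min_G \|\tilde{X}_i^{\mathrm{anc}} G - Z\|_F,$$

so that the re-projected anchors approximately coincide:
$\tilde{X}_i^{\mathrm{anc}} G_i \approx \tilde{X}_j^{\mathrm{anc}} G_j$.
The *collaborative representation* $\hat{X}_i = \tilde{X}_i G_i \in
\mathbb{R}^{m_i \times k}$ is stacked sample-wise across workers and
analysed as a single dataset. `anchor_alignment_residual()` reports the
pairwise Frobenius mismatch of the re-projected anchors as a quality
diagnostic.

The API enforces the confidentiality boundary structurally:
`worker_encode()` returns a `share` (intermediate data, anchor image,
labels) and a `map` that stays at the institution; the master-side
functions (`compute_collaboration_maps()`, `master_collaborate()`) accept
only shares.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `l` | `min(d-1, ceil(0.75 d))` (15 for d = 20) | worker compression dimension |
| `k` | `min(l_i)` | integrated dimension; at most the smallest worker dimension |
| `r` | 1000 | anchor rows; must comfortably exceed every `l_i` so the alignment least squares is overdetermined |
| anchor strategy | `"uniform"` | uniform over public reference ranges; `"resample"` interpolates rows of a public reference table |
| `scale.` | `TRUE` in the pipeline | standardise columns inside `f_i` (see below) |
| LR penalty | L1, `C = 1` | inverse-strength convention; `lambda = 1/(C n)` on the penalised-likelihood scale |
| GBDT | depth unlimited, 31 leaves, eta 0.1, 100 rounds | untuned reference settings |
| test split | 99 samples | drawn from the checkup cohort each replicate |
| replicates | 100 | bootstrap repetitions per cell |

**Why scaling is on by default in the pipeline.** The encoded matrix mixes
units: red-cell counts around 450, lipids around 100, HbA1c around 6, and
0/1 ordinals. Covariance PCA on such a matrix ranks directions by raw
variance and, at `l = 15` of 20, discards precisely the low-variance
columns — HbA1c, urinary protein, sex — which carry most of the diabetes
signal. The primitive `fit_intermediate_map()` defaults to classical
covariance PCA (and its closed-form behaviour is tested that way), but
`worker_encode()` and the experiment harness set `scale. = TRUE`,
performing PCA on the correlation scale. The scaling vector is part of the
worker's private map, so the shared anchor passes through the same
standardisation.

Other numerical choices: every singular/principal direction is oriented so
its largest-magnitude entry is positive (deterministic output across
platforms); the alignment least squares is solved by QR on the anchor
images after an explicit rank check (rank below `k` is rejected with a
diagnostic rather than silently regularised); the L1 logistic fit descends
a 25-step decreasing lambda path to the target value because a cold
single-lambda fit is unreliable on near-separable, heavily imbalanced
subsets.

## The cleaning pipeline

`preprocess_institution()` applies, in order: (1) per-year aggregation of
repeated visits — mean for quantitative features, mode for qualitative
ones, ties resolved to the most benign category; (2) an observation-window
filter keeping samples measured at least once in both 2014 and 2015; (3)
outcome labelling over 2016–2018 — a sample is retained only if HbA1c and
FPG were measured together on at least one occasion and labelled diabetic
if, on such an occasion, HbA1c ≥ 6.5% and FPG ≥ 126 mg/dl simultaneously;
(4) removal of features missing in ≥ 50% of observation-window cells; (5)
removal of samples carrying fewer than half of the surviving feature
cells, assessed *before* imputation (afterwards nothing is missing and the
filter would be vacuous); (6) mean/mode imputation. Encoding then yields
one column per year-varying feature and observation year, dipstick
readings as ordinals 0–4, sex as a single 0/1 column, and age once from
the first observation year: 9 × 2 + 2 = 20 columns for the default study.

Two deliberate readings of ambiguous points: threshold co-occurrence is
assessed per *visit* when visit-level records are available (the two
markers come from the same blood draw), per yearly row otherwise — both
paths are exposed; and imputation is performed once per institution before
any train/test split, matching how a registry would publish a completed
table — the leakage through column means from the 99 test rows is
negligible at these sizes, and it keeps the model-ready matrix free of
missing values for every analysis mode.

Feature filtering is per institution, so the surviving sets may differ
(fasting glucose and urinary glucose fall in the checkup profile, casual
glucose and creatinine in the hospital profile); the collaboration then
uses the intersection, since the workers must agree on $d$.

## What the generator emulates — and what it does not

`generate_institution()` draws a per-sample outcome class from the
profile's prevalence (43/1399 checkup, 209/1502 hospital), then per visit:
quantitative features from class-conditional Gaussians (means/SDs follow
the published cohort statistics of the eleven retained features, clipped
at zero), qualitative features from class-conditional frequencies, one
visit per year for the checkup profile and 1 + Poisson(2) for the
hospital. Age advances deterministically by calendar year; sex is fixed
per sample. During 2016–2018 the two diagnostic markers switch to an
outcome-trajectory model: positive samples are drawn at or above both
thresholds on every occasion, negative samples strictly below at least one
— so the labelling stage can recover the generating class exactly, which
makes label recovery a testable property rather than a statistical
accident. Missingness is completely at random per value; the checkup rates
for FPG (0.55) and urinary glucose (0.60) sit above the filter threshold
by construction, and the hospital rates for casual glucose and creatinine
are 0.88 because with ~3 visits per year a yearly cell is missing only
when all visits are (the visit rate must satisfy
$E[\mathrm{rate}^V] \ge 0.5$).

Not emulated: inter-feature correlation (features are independent given
class), informative missingness, longitudinal autocorrelation outside the
outcome window, and the hospital's ~4000 non-common data items. Passing
tests therefore certify the pipeline's mechanics and the collaboration's
algebra on data with the published first and second moments — they do not
certify performance on the real registries.

## A limitation worth stating plainly

On the real cohorts, pooling the hospital data through the collaboration
improved small-sample logistic regression markedly (the real
quarter-sample baseline sat near AUC 0.69). The synthetic analogue behaves
differently for an identifiable reason: under class-conditionally
independent Gaussians at the published means and SDs, the checkup cohort
is close to linearly separable — haemoglobin alone separates the classes
by about 2.3 SD — so the individual baseline already reaches AUC ≈ 0.96 at
quarter size, while the hospital statistics make haemoglobin uninformative
(12.9 vs 13.0). Adding 1500 hospital samples then *dilutes* the checkup's
dominant predictor: dc-mode lands near 0.94. The middle analysis stays
within 0.02 of the individual one (the confidentiality transform itself
costs little, as in the real study), but the synthetic dc-vs-individual
gain is typically negative. We kept the published statistics as the
generator's ground truth rather than reshaping them until the known
qualitative result reappeared; the corresponding end-to-end check fails
honestly and the test suite documents it.

## Problem sizes used by the tests

Unit tests run on cohorts of a few hundred samples. The end-to-end checks
use the full default cohorts (1399/1502 profiles, ~1150/1500 retained),
100 bootstrap replicates per cell, 100 master seeds for the
quarter-sample comparison, and the complete 3 × 3 × 2 grid twice for the
determinism check — sizes chosen so the whole suite completes in well
under half an hour on one CPU.

## Worked example

```{r example}
library(dcollab)

profs <- default_profiles()
checkup <- generate_institution(profs$checkup, seed = 11)
hospital <- generate_institution(profs$hospital, seed = 12)

prep <- prepare_datasets(checkup, hospital)
prep$preps$checkup          # per-stage sample/feature counts

grid <- run_experiment_grid(prep$checkup, prep$hospital,
                            subsets = "quarter", models = "lr_l1",
                            n_replicates = 100, seed = 1)
subset(grid$summary, metric == "auc")
improvement_table(run_experiment_grid(prep$checkup, prep$hospital,
                                      models = "lr_l1",
                                      n_replicates = 100, seed = 1)$summary)
```
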