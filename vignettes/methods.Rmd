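---
title: "Methods: multi-learning treatment-sensitivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-learning treatment-sensitivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(multsens)
```

This vignette is the package's own account of the model it implements:
the assumptions behind each stage, the tunable parameters and their
defaults, the numerical conventions adopted where the procedure is
underdetermined, what the synthetic data generator does and does not
emulate, and the known limitations.

## The prediction problem

The unit of analysis is a newly diagnosed multiple-myeloma patient
described by (i) clinical markers (mixed nominal, ordinal and numeric),
(ii) a bulk gene-expression profile, and (iii) the first-line
treatment, where "Non-treatment" is itself a valid label. The outcome
is *treatment sensitivity* (TS), a binary variable derived from the six
ordered treatment-response classes PD < SD < PR < VGPR < CR < SCR. The
model estimates `P(sensitive | clinical, expression, treatment)`; since
treatment is an input, the fitted model supports the counterfactual
question "which treatment would maximize this patient's predicted
sensitivity?".

## Outcome definition

Five binary cuts are possible over six ordered classes. Each cut is
scored by how well it stratifies days-to-disease-progression survival:
a Cox proportional-hazards model with the cut as its only covariate,
summarized by the score test (equivalent to the log-rank test for a
single binary covariate without ties). The minimum-p cut wins. Two
conventions worth noting:

* the class order used for cutting is the clinical depth-of-response
  order, which places SCR above CR — this is what makes the familiar
  "{CR, SCR} = sensitive" definition one of the five candidates;
* ties are handled with Breslow's approximation, and a cut that leaves
  one arm without events is scored p = 1 with a warning rather than
  failing, so degenerate candidates lose rather than crash the scan.

## Preprocessing

Nominal markers expand to one 0/1 column per level; ordinal markers map
to 1, 2, 3, … in their declared order; missing values become zero.
Marker-level missingness is measured *before* zero-imputation and
markers above 10% missing are dropped — measuring after imputation
would make the rule vacuous. Patients without a response class are
dropped first, then treatments with fewer than 10 patients (their
strata are too small for fold construction). Patient order is
lexicographic by id everywhere, which makes every downstream stage
order-independent and reproducible.

All markers are min–max normalized with bounds learned on training data
only. Validation data is clipped into [0, 1]; training data is not (it
attains 0 and 1 exactly). A constant marker maps to 0 by convention:
the formula's denominator vanishes, and a constant carries no
information either way.

## Marker selection

Relevance is a per-marker two-sample Kolmogorov–Smirnov test between
the sensitive and non-sensitive classes; redundancy is absolute Pearson
correlation above `beta` between two surviving markers, resolved by
keeping the smaller p-value. The scan processes markers in ascending
p-value order (ties broken lexicographically by name). This ordering is
a package decision — the procedure itself does not fix an order — and
it has two consequences we consider desirable: the kept member of any
correlated group is its most significant representative, and the
outcome is deterministic. Three further conventions: an
already-excluded marker is skipped both as an anchor and as a
comparison partner; an anchor excluded inside its own comparison loop
stops comparing; Pearson correlation with a zero-variance vector is
defined as 0. P-values are computed once per marker and cached.

Because the inner loop only visits not-yet-analysed markers, two
survivors whose comparison was never reached can in principle remain
correlated; the scan is single-pass by design and the test suite pins
its behavior to an independent replay of the same procedure rather
than to a "no correlated survivors" guarantee, which the single-pass
procedure does not make.

Defaults: `alpha = 0.05` (conventional, configurable), `beta = 0.75`.

## Feature extraction

Three views are computed from the selected genes `G'`:

* **Profiling distances `L`** — k-means over patients; each patient is
  represented by its Euclidean distance to each of the `o` centroids.
* **Gene-cluster means `E`** — k-means over genes (the transposed
  matrix); each patient is represented by its mean expression per gene
  cluster.
* **Denoised genes `G^d`** — a symmetric autoencoder (widths
  `[i, ⌊.5i⌋, ⌊.4i⌋, ⌊.3i⌋, ⌊.4i⌋, ⌊.5i⌋, i]`, ReLU hidden units,
  linear output) trained to reconstruct the clean input from an input
  corrupted with fresh additive N(0, 1) noise each epoch, minimizing
  MSE + L2 (scale 0.01) with full-batch AdaDelta (rho = 0.95,
  eps = 1e−6). Training stops after `patience` epochs without a new
  minimum MSE (default 1000) or at `max_epochs` (default 5000), and the
  weights at the minimum are kept. Resampling the corruption per epoch
  is standard denoising-autoencoder practice; the alternative (fixed
  noise per sample) anchors the model to one noise draw.

Cluster counts are chosen by maximizing
`SCM(c) = (mean(SC) − sd(SC)) / (sd(cluster sizes) + 1)` over
`c = 2, 3, …`, stopping after 10 consecutive non-improving counts.
Conventions: both standard deviations are population standard
deviations (a single cluster-size vector has no natural "sample"
version); silhouettes use Euclidean distance, matching the profiling
distances; arg-max ties go to the smallest count (parsimony); k-means
uses 10 restarts under a fixed seed because the restart noise otherwise
propagates into the count choice. The gene-side count `k` is selected
by an independent SCM scan on the transposed matrix rather than reusing
the patient-side `o`; the two axes have no reason to share a count.

At validation time, patients are projected onto the *training*
centroids and the *training* gene-cluster assignments — nothing is
refit. The extracted blocks are themselves min–max normalized (bounds
from training data, validation clipped) before entering the
classifier, keeping every feature on the same scale as the raw marker
blocks; tree ensembles are insensitive to this, but it keeps the
feature matrix uniform for any backend.

## Classifier and hyperparameter optimization

The supervised head is a gradient-boosted-tree ensemble. Tuning
minimizes validation log loss: one stratified half of the training data
trains each candidate, the other half scores it. The optimizer draws 10
random configurations, then fits a Gaussian-process surrogate
(Matérn-5/2 kernel on the unit-cube encoding of the space; length-scale
and noise chosen by marginal likelihood over a small grid) and spends
50 more evaluations on expected-improvement maximizers (256 random
candidates per iteration). A failed or non-finite evaluation is
recorded as infinite loss and enters the surrogate as the worst finite
loss observed. The returned configuration is the arg-min of all
observed losses, so it can never be worse than the best random draw.

With the tuned configuration, the training data is split into three
stratified folds and one model is trained per pairwise fold union, each
with early stopping on its held-out third (stop after 1 boosting
iteration without log-loss improvement, cap 100). The TS score is the
arithmetic mean of the three member scores. The decision threshold is
the midpoint between adjacent sorted unique training scores that
maximizes Youden's J (sensitivity + specificity − 1); "the threshold
with the highest AUC" is not well defined since AUC is threshold-free,
and the Youden point is the standard reading. Ties take the lower
threshold; all-equal scores return that value with J = 0. Log loss is
clipped at 1e−15.

The boosted-tree backend is xgboost with histogram binning and
leaf-wise (`lossguide`) growth, which reproduces the leaf-wise tree
shape the hyperparameter list describes. The tuned space keeps the
published parameter names; ranges are standard practitioner ranges
(the source procedure names the parameters but prints no ranges):

| parameter | range | backend mapping |
|---|---|---|
| num_leaves | 2–128 | max_leaves |
| scale_pos_weight | 0.5–10 (log) | scale_pos_weight |
| min_child_samples | 5–100 | *(no xgboost counterpart; carried, inert)* |
| bin_construct_sample_cnt | 1e3–2e5 | *(no counterpart; carried, inert)* |
| max_bin | 32–255 | max_bin |
| min_sum_hessian_in_leaf | 1e−3–10 (log) | min_child_weight |
| bagging_fraction | 0.5–1 | subsample |
| feature_fraction | 0.5–1 | colsample_bytree |
| feature_fraction_bynode | 0.5–1 | colsample_bynode |

The baseline pipeline (SMLA) runs selection, tunes a single classifier
(boosted trees; or an MLP via nnet — single hidden layer, BFGS, so the
learning-rate parameters are likewise carried but inert; or an SVM via
e1071 with C, gamma, degree and kernel mapped exactly), then refits on
all training data and applies the same threshold rule. For TS
prediction the baseline sees the same inputs as the full pipeline
(selection over the concatenated clinical+gene matrix, one-hot
treatment appended after selection), so comparisons are like-for-like.

## Cross-validation and evaluation

Folds are stratified by treatment × TS. Within each treatment stratum
the majority class is randomly undersampled to the minority count
(undersampling, not duplication, so no patient appears twice), and one
patient of each class at a time is dealt to the folds. This makes the
sensitive/non-sensitive counts *exactly* equal within every
fold × stratum cell; the price is that per-stratum fold sizes can
differ by two rather than one. Each fold's pipeline — normalization
bounds, selection, clustering, denoiser, tuning, ensemble, threshold —
is fit on the other nine folds only; the test suite verifies that
corrupting the held-out patients changes no fitted artifact
byte-for-byte.

AUC uses the Mann–Whitney rank formulation (exact, deterministic under
ties). Accuracy, sensitivity and specificity use each fold's own
training-derived threshold; pooled metrics combine all validation folds
into one set. Per-fold AUC vectors of two pipelines run under the same
plan are compared with a two-sample t-test. The marker-relationship
graph aggregates per-fold selection reports: node size = number of
rounds selected, edges weighted by co-selection counts, zero-weight
edges omitted.

## Treatment simulation

For each validation patient the treatment one-hot block is replaced by
each candidate treatment in turn and the TS score recomputed; all other
features are untouched and the cohort is never mutated. The
score-maximizing treatment κ breaks exact ties conservatively: if the
actual treatment is among the maximizers it is kept, so a
treatment-blind model reports zero switches; otherwise the
lexicographically first maximizer wins. Simulations run per CV fold
with that fold's model on its validation patients and are pooled.

## The synthetic cohort generator

The generator is the package's study bench. Its defaults are the study
conditions used throughout the tests: 600 patients; five treatments
with uneven prevalence (weights 133/64/236/50/232, including
"Non-treatment"); sensitive fraction 0.30; 500 genes of which 10 are
informative with a 1-standard-deviation (log-scale) shift between
classes, each with one near-duplicate copy (log-scale noise sd 0.01);
20 clinical markers of which 5 are informative; 5% missing clinical
values; exponential progression times with hazard ratio 3 between
classes (baseline median 700 days) and 20% censoring. Response classes
are assigned by thresholding a latent propensity into six bins such
that the sensitive class is exactly {CR, SCR}, so the planted outcome
and the class cut are mutually consistent. Gene abundances are
log-normal, mimicking RNA-seq skew while staying distribution-agnostic
(the KS test and tree splits are invariant to the monotone transform).
Missingness is injected into clinical markers only, since expression
enters the pipeline as a complete quantified matrix. An optional
treatment × biomarker interaction marks a random half of patients as
"responsive": their interaction genes shift by `marker_shift` and
their log-odds of sensitivity increase by `shift` under one designated
treatment, giving them a recoverable latent optimal treatment. An
optional FISH panel derives binary cytogenetic-style markers from
weighted driver-gene scores with configurable noise and prevalence.

What the generator does *not* emulate: real marginal distributions or
gene identities, batch effects, treatment assignment confounded by
prognosis, non-proportional hazards, correlated missingness, or
measurement platform noise. Passing tests therefore demonstrate that
the machinery recovers planted structure under its own assumptions —
not that any particular clinical performance level transfers to real
cohorts.

## Problem sizes and budgets used by the tests

The test suite and the acceptance script run reduced optimization
budgets (5 random + 10 surrogate-guided evaluations, denoiser patience
100 with cap 500, cluster scan capped at 10) and cohorts of 400–1200
patients with 100–500 genes. These sizes were chosen so that each
statistical check has a comfortable margin: e.g. the null-calibration
check uses cohorts of 1200 so the pooled validation AUC has standard
error ≈ 0.02 against an acceptance band of ±0.05. The defaults in
`mult_control()` (10 + 50 evaluations, patience 1000) are the full
published settings.

## Known limitations

* The single-pass redundancy scan can, in principle, leave a correlated
  pair both selected when their comparison is never reached; we
  reproduce the procedure as specified rather than adding a second
  pass.
* Two boosted-tree hyperparameters and two MLP hyperparameters have no
  counterpart in the available backends and are carried inertly (table
  above).
* The simulation is a pure score arg-max; it makes no causal
  adjustment for treatment assignment, so reallocation tables describe
  the model, not an estimated treatment effect.
* TS scores are not calibrated probabilities; the threshold rule
  consumes ranks, and downstream users should not read the scores as
  risks.
* Expression is taken as given (no transformation is applied before
  normalization); whether to pre-transform is left to the caller.
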