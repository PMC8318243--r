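# multsens

Predicting **treatment sensitivity (TS)** in newly diagnosed multiple
myeloma from clinical markers, bulk gene expression and the first-line
treatment — and simulating, per patient, which treatment would maximize
the predicted sensitivity.

The package is aimed at computational biologists and biostatisticians
working with cohorts of the CoMMpass type: a patient-by-marker clinical
table (mixed nominal/ordinal/numeric), a patient-by-gene expression
matrix, a first-line treatment label, the six ordered treatment-response
classes **PD < SD < PR < VGPR < CR < SCR**, and (for a subset) days to
disease progression with an event flag. Because such cohorts are access
restricted, the package ships a synthetic cohort generator with planted
ground truth, so every stage is testable and every reported number is
reproducible from code alone.

## The method

**Outcome.** TS is a binary cut over the ordered response classes. Among
the five possible cuts, the one whose two groups best stratify
days-to-disease-progression survival (minimum Cox score-test p-value) is
chosen; on realistic data this groups **{CR, SCR}** as *sensitive*.

**Marker selection.** With `F` the patients-by-markers matrix and `c`
the TS class vector, each marker is scored with a two-sample
Kolmogorov–Smirnov test between classes; markers with `p > α` are
dropped. Surviving markers are compared pairwise and, when
`|Pearson r| > β` (default `β = 0.75`), the member with the larger
p-value is dropped as redundant. This runs independently over genes
(`G′`) and clinical markers (`C′`).

**Feature extraction.** Three unsupervised/self-supervised views of the
selected genes:

* *Genetic profiling* `L`: Euclidean distances from each patient to the
  `o` k-means centroids in selected-gene space;
* *Gene clustering* `E`: per-patient mean expression of each of the `k`
  gene clusters (k-means on the transposed matrix);
* *Gene denoising* `G^d`: reconstruction by a seven-layer denoising
  autoencoder with widths `[i, ⌊.5i⌋, ⌊.4i⌋, ⌊.3i⌋, ⌊.4i⌋, ⌊.5i⌋, i]`,
  trained with additive N(0, 1) input corruption, AdaDelta and an L2
  penalty.

`o` and `k` are chosen by maximizing the silhouette-based metric
`SCM(c) = (mean(SC) − sd(SC)) / (sd(cluster sizes) + 1)` over
`c = 2, 3, …` with a 10-step stall rule.

**Predictor.** A gradient-boosted-tree ensemble over the concatenation
`G′ | C′ | L | E | G^d | T` (`T` = one-hot treatment). Hyperparameters
are tuned by Gaussian-process Bayesian optimization of the validation
log loss on half of the training data; the training data is then split
into three folds and one model is trained per pairwise fold union with
early stopping on the held-out third. The TS score is the mean of the
three member scores; the decision threshold maximizes Youden's J on
training data. A simplified baseline (**SMLA**: selection → Bayesian
optimization → a single boosted-tree/MLP/SVM classifier) is included
for benchmarking.

**Simulation.** For each patient, the treatment one-hot block is
overwritten with every candidate treatment and the TS score recomputed;
`κ = argmax` over candidates, and the switch fraction is the share of
patients with `κ ≠` actual treatment.

## Worked example

```r
library(multsens)

cohort <- generate_cohort(synth_config(n_patients = 300, n_genes = 200,
                                       seed = 42)) |>
  filter_cohort()
cohort
#> <mult_cohort> 300 patients, 20 clinical markers, 200 genes
#> treatments: Bor-Cyc-Dex (57), Bor-Dex (22), Bor-Len-Dex (100),
#>             Len-Dex (23), Non-treatment (98)

# survival-guided sensitivity definition: five candidate cuts
def <- select_ts_definition(cohort$patients$response,
                            cohort$patients$ddp_days,
                            cohort$patients$ddp_event)
def
#> <ts_definition> sensitive = {CR, SCR}
tidy(def)
#>   sensitive_from n_sensitive n_non_sensitive  p_value
#> 1 SD                     252              48 6.75e- 3
#> 2 PR                     199             101 2.31e- 4
#> 3 VGPR                   150             150 3.04e- 6
#> 4 CR                      98             202 3.20e-10   <- chosen
#> 5 SCR                     45             255 8.78e- 5

# equalized cross-validation of the full pipeline
ts    <- derive_ts(cohort$patients$response, def)
ctrl  <- mult_control(bo_init = 5, bo_iter = 10, denoise_patience = 100,
                      denoise_max_epochs = 500, ncs_cmax = 10)
plan  <- make_cv_plan(cohort, n_folds = 5, ts = ts, seed = 42)
cv    <- run_cv(cohort, plan, "mult", seed = 42, control = ctrl,
                simulate = TRUE)
glance(cv)
#>   pipeline     n   auc accuracy sensitivity specificity mean_fold_auc
#> 1 mult       196 0.982    0.913       0.888       0.939         0.983
```

The pooled validation AUC (0.982 here) is high because the synthetic
cohort plants a strong 1-sd signal in ten genes and five clinical
markers; permuting the labels drops it to ~0.5 (see the test suite).
The per-fold simulation pools into a reallocation table:

```r
cv$simulation
#> <mult_simulation> 196 patients, switch fraction 29.08%
round(reallocation_matrix(cv$simulation), 1)
#>                simulated
#> actual          Bor-Cyc-Dex Bor-Dex Bor-Len-Dex Len-Dex Non-treatment
#>   Bor-Cyc-Dex         100.0     0.0         0.0     0.0           0.0
#>   Bor-Dex              16.7    83.3         0.0     0.0           0.0
#>   Bor-Len-Dex          37.8     0.0        62.2     0.0           0.0
#>   Len-Dex              38.9     0.0         5.6    55.6           0.0
#>   Non-treatment        27.1     0.0         1.4     0.0          71.4
```

Each row is an actual treatment and sums to 100%: the diagonal is the
share of patients whose actual treatment already maximizes their
predicted sensitivity. `autoplot()` methods exist for selection
reports, SCM traces, optimization traces, CV results and simulations;
`run_pipeline()` performs the whole experiment (filter → outcome
definition → CV → simulation) and writes all tables plus a manifest,
and `inst/cli/multsens.R` wraps it for shell use.

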