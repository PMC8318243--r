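test_that("the generator is deterministic and honors its config", {
  cfg <- synth_config(n_patients = 120, n_genes = 50,
                      n_informative_genes = 5, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)

  # response bins are consistent with the planted sensitivity class
  expect_identical(derive_ts(a$patients$response), a$ground_truth$ts)

  # redundant copies are near-duplicates of their sources
  map2 <- a$ground_truth$redundant_map
  expect_gt(nrow(map2), 0)
  for (i in seq_len(nrow(map2))) {
    r <- cor(a$expression[[map2$copy[i]]], a$expression[[map2$source[i]]])
    expect_gt(r, 0.99)
  }
})

test_that("marginal sensitivity prevalence tracks the configured fraction", {
  co <- generate_cohort(synth_config(n_patients = 2000, n_genes = 5,
                                     n_informative_genes = 0,
                                     sensitive_fraction = 0.3, seed = 21))
  expect_lt(abs(mean(co$ground_truth$ts) - 0.3), 0.05)
})

test_that("zero effect size yields null genes indistinguishable by the KS test", {
  co <- generate_cohort(synth_config(n_patients = 150, n_genes = 200,
                                     n_informative_genes = 10,
                                     effect_size = 0, seed = 33))
  ts <- co$ground_truth$ts
  expr <- as.matrix(co$expression[-1])
  pv <- apply(expr, 2, function(x) ks_pvalue(x[ts == 0], x[ts == 1]))
  # p-values approximately uniform: no mass near zero beyond chance
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(sensitive_fraction = 0), "config error")
  expect_error(synth_config(n_genes = 10, n_informative_genes = 8,
                            n_redundant_copies = 1), "config error")
  expect_error(synth_config(n_clinical_markers = 3,
                            n_informative_clinical = 5), "config error")
  expect_error(synth_config(interaction = list(treatment = "nope",
                                               n_markers = 1, shift = 1,
                                               marker_shift = 1)),
               "config error")
})

test_that("survival times separate by the planted sensitivity class", {
  co <- generate_cohort(synth_config(n_patients = 800, n_genes = 5,
                                     n_informative_genes = 0,
                                     hazard_ratio = 3, censoring_frac = 0.2,
                                     seed = 5))
  ts <- co$ground_truth$ts
  d <- co$patients
  expect_gt(median(d$ddp_days[ts == 1]), median(d$ddp_days[ts == 0]))
  expect_lt(abs(mean(1 - d$ddp_event) - 0.2), 0.08)
})

test_that("FISH panel prevalence and noiseless recoverability hold", {
  co <- generate_cohort(synth_config(n_patients = 1000, n_genes = 40,
                                     n_informative_genes = 0, seed = 13))
  panel <- generate_fish_panel(co, n_markers = 3, genes_per_marker = 5,
                               prevalence = 0.3, noise_sd = 0, seed = 2)
  for (nm in names(panel$drivers)) {
    expect_lt(abs(mean(panel$fish[[nm]]) - 0.3), 0.05)
    # noiseless: the call is an exact function of the driver score
    z <- scale(log(as.matrix(co$expression[panel$drivers[[nm]]]) + 1))
    score <- drop(z %*% panel$weights[[nm]])
    expect_identical(panel$fish[[nm]],
                     as.integer(score > quantile(score, 0.7)))
  }
  expect_error(generate_fish_panel(co, driver_gene_sets = list(character(0))),
               "config error")
  expect_error(generate_fish_panel(co, driver_gene_sets = list("ghost")),
               "config error")
})

test_that("a driver-free FISH marker is unpredictable from expression", {
  co <- generate_cohort(synth_config(n_patients = 300, n_genes = 60,
                                     n_informative_genes = 0, seed = 17))
  panel <- generate_fish_panel(co, n_markers = 1, n_null_markers = 1,
                               noise_sd = 0.3, seed = 3)
  tr <- 1:200
  te <- 201:300
  expr <- as.matrix(co$expression[-1])
  norm <- fit_normalizer(expr[tr, ])
  xtr <- apply_normalizer(expr[tr, ], norm)
  xte <- apply_normalizer(expr[te, ], norm, clip = TRUE)

  y <- panel$fish$fish_null01
  fit <- train_smla(xtr, y[tr], model = "gbt", alpha = 0.2,
                    seed = 1, control = quick_control())
  auc_null <- multsens:::auc_mw(y[te], predict(fit, xte)$score)
  expect_gt(auc_null, 0.3)
  expect_lt(auc_null, 0.7)

  # while a driver-based marker with mild noise is clearly learnable
  y2 <- panel$fish$fish01
  fit2 <- train_smla(xtr, y2[tr], model = "gbt", alpha = 0.2,
                     seed = 1, control = quick_control())
  expect_gt(multsens:::auc_mw(y2[te], predict(fit2, xte)$score), 0.8)
})
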