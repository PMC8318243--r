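# Minimal stand-in predictors for simulation tests: simulate_treatments()
# only needs a `treatments` field and a predict(model, cohort, treatment =)
# method.

predict.blind_model <- function(object, cohort, treatment = NULL, ...) {
  tibble::tibble(score = rep(0.5, n_patients(cohort)))
}

predict.pref_model <- function(object, cohort, treatment = NULL, ...) {
  trt <- if (length(treatment) == 1) {
    rep(treatment, n_patients(cohort))
  } else treatment
  # score is highest under each patient's latent preferred treatment
  tibble::tibble(score = 0.4 + 0.3 * (trt == object$pref))
}

registerS3method("predict", "blind_model", predict.blind_model,
                 envir = asNamespace("stats"))
registerS3method("predict", "pref_model", predict.pref_model,
                 envir = asNamespace("stats"))
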