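#' Build a class- and treatment-equalized cross-validation plan
#'
#' Splits patients into `n_folds` disjoint folds stratified by
#' treatment x sensitivity.  Within each treatment stratum, the majority
#' sensitivity class is first randomly undersampled down to the minority
#' count (the removed patients are logged, not scored), then one patient
#' of each class at a time is dealt to the folds, so every fold holds
#' equal sensitive and non-sensitive counts within every treatment
#' stratum.  A stratum missing one class entirely cannot be equalized;
#' its patients are removed with a warning.
#'
#' @param cohort A complete [mult_cohort()].
#' @param n_folds Number of folds.
#' @param ts Binary outcome; defaults to deriving it from the response
#'   classes with the standard definition.
#' @param seed Integer seed.
#' @return A `cv_plan`: tibble with `patient_id`, `treatment`, `ts`,
#'   `fold` (`NA` for removed patients) and `removed`; attribute
#'   `equalization_log`.
#' @export
make_cv_plan <- function(cohort, n_folds = 10, ts = NULL, seed = 1) {
  if (is.null(ts)) ts <- derive_ts(cohort$patients$response)
  plan <- tibble(patient_id = cohort$patients$patient_id,
                 treatment = cohort$patients$treatment,
                 ts = as.integer(ts),
                 fold = NA_integer_, removed = FALSE)
  log <- list()
  with_seed(seed, {
    for (tr in sort(unique(plan$treatment))) {
      i1 <- which(plan$treatment == tr & plan$ts == 1)
      i0 <- which(plan$treatment == tr & plan$ts == 0)
      m <- min(length(i1), length(i0))
      if (m == 0) {
        warn(paste0("treatment ", tr,
                    " lacks one sensitivity class; its patients are removed"))
        plan$removed[c(i1, i0)] <- TRUE
        next
      }
      k1 <- sample(i1, m)
      k0 <- sample(i0, m)
      dropped <- setdiff(c(i1, i0), c(k1, k0))
      if (length(dropped) > 0) {
        plan$removed[dropped] <- TRUE
        log[[length(log) + 1]] <- tibble(
          treatment = tr,
          majority_class = if (length(i1) > length(i0)) 1L else 0L,
          n_removed = length(dropped))
      }
      ## deal one patient of each class per slot: exact class equality
      ## within every fold x stratum cell
      offset <- sample.int(n_folds, 1)
      fold_seq <- ((offset + seq_len(m) - 2) %% n_folds) + 1
      plan$fold[k1] <- fold_seq
      plan$fold[k0] <- fold_seq
    }
  })
  plan$removed[is.na(plan$fold)] <- TRUE
  class(plan) <- c("cv_plan", class(plan))
  attr(plan, "equalization_log") <-
    if (length(log) > 0) bind_rows(log) else
      tibble(treatment = character(), majority_class = integer(),
             n_removed = integer())
  attr(plan, "n_folds") <- n_folds
  attr(plan, "seed") <- seed
  plan
}

#' Run a cross-validated pipeline experiment
#'
#' For each fold, the complete chosen pipeline (normalization, marker
#' selection, feature extraction, hyperparameter optimization, ensemble
#' training, threshold) is fitted on the remaining folds only, and the
#' held-out fold is scored.  Passing the same `plan` to different
#' pipelines compares them under identical raw data and fold
#' arrangements.
#'
#' @param cohort A complete [mult_cohort()].
#' @param plan A [make_cv_plan()]; its `ts` column is the outcome.
#' @param pipeline `"mult"`, `"smla-gbt"`, `"smla-mlp"` or `"smla-svm"`.
#' @param seed Integer seed for the per-fold pipelines.
#' @param control A [mult_control()].
#' @param simulate Also run the counterfactual treatment simulation with
#'   each fold's model on its validation patients (`"mult"` only).
#' @param keep_models Retain the fitted per-fold models.
#' @return A `mult_cv`: `scores` (per-patient validation scores),
#'   `metrics` (list: `per_fold`, `pooled`, `per_treatment`),
#'   `selections` (per-fold selection reports), `failures`, optionally
#'   `models` and `simulation`.
#' @export
run_cv <- function(cohort, plan, pipeline = c("mult", "smla-gbt",
                                              "smla-mlp", "smla-svm"),
                   seed = 1, control = mult_control(), simulate = FALSE,
                   keep_models = FALSE) {
  pipeline <- match.arg(pipeline)
  n_folds <- attr(plan, "n_folds")
  stopifnot(identical(plan$patient_id, cohort$patients$patient_id))

  scores <- list()
  selections <- list()
  models <- list()
  sims <- list()
  failures <- character(0)

  for (f in seq_len(n_folds)) {
    tr_idx <- which(!plan$removed & plan$fold != f)
    va_idx <- which(!plan$removed & plan$fold == f)
    if (length(va_idx) == 0) next
    res <- tryCatch(
      run_one_fold(cohort, plan, pipeline, tr_idx, va_idx, f,
                   derive_seed(seed, paste0("fold", f)), control, simulate),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0("fold ", f, ": ", conditionMessage(res)))
      next
    }
    scores[[f]] <- res$scores
    selections[[paste0("fold", f)]] <- res$selection
    if (keep_models) models[[paste0("fold", f)]] <- res$model
    if (!is.null(res$simulation)) sims[[f]] <- res$simulation
  }
  if (length(scores) == 0) {
    abort(paste0("all folds failed: ", paste(failures, collapse = "; ")))
  }
  scores <- bind_rows(scores)

  per_fold <- scores |>
    group_by(.data$fold) |>
    summarise(confusion_metrics(.data$ts, .data$score,
                                .data$threshold[1]),
              .groups = "drop")
  pooled <- bind_cols(
    tibble(n = nrow(scores), auc = auc_mw(scores$ts, scores$score)),
    pooled_confusion(scores))
  per_treatment <- scores |>
    group_by(treatment = .data$treatment) |>
    summarise(n = n(), auc = auc_mw(.data$ts, .data$score),
              pooled_confusion(dplyr::pick(dplyr::everything())),
              .groups = "drop")

  out <- structure(
    list(pipeline = pipeline, scores = scores,
         metrics = list(per_fold = per_fold, pooled = pooled,
                        per_treatment = per_treatment),
         selections = selections, failures = failures, plan = plan),
    class = "mult_cv")
  if (keep_models) out$models <- models
  if (length(sims) > 0) out$simulation <- pool_simulations(sims)
  out
}

# accuracy/sensitivity/specificity from per-fold hard labels (each fold's
# own training-derived threshold)
pooled_confusion <- function(scores) {
  tp <- sum(scores$class == 1 & scores$ts == 1)
  tn <- sum(scores$class == 0 & scores$ts == 0)
  fp <- sum(scores$class == 1 & scores$ts == 0)
  fn <- sum(scores$class == 0 & scores$ts == 1)
  tibble(accuracy = (tp + tn) / nrow(scores),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

run_one_fold <- function(cohort, plan, pipeline, tr_idx, va_idx, fold,
                         seed, control, simulate) {
  train <- cohort_subset(cohort, tr_idx)
  val <- cohort_subset(cohort, va_idx)
  ts_tr <- plan$ts[tr_idx][order(cohort$patients$patient_id[tr_idx])]
  ts_va <- plan$ts[va_idx][order(cohort$patients$patient_id[va_idx])]

  if (pipeline == "mult") {
    model <- train_mult(train, ts = ts_tr, seed = seed, control = control)
    pred <- predict(model, val)
    selection <- list(clinical = model$sel_clin, gene = model$sel_gene)
    threshold <- as.numeric(model$tspt$threshold)
    sim <- if (simulate) simulate_treatments(model, val) else NULL
  } else {
    backend <- sub("smla-", "", pipeline)
    comb_tr <- cbind(df_to_matrix(train$clinical),
                     df_to_matrix(train$expression))
    comb_va <- cbind(df_to_matrix(val$clinical),
                     df_to_matrix(val$expression))
    norm <- fit_normalizer(comb_tr)
    vocab <- sort(unique(cohort$patients$treatment))
    model <- train_smla(apply_normalizer(comb_tr, norm),
                        ts_tr, model = backend,
                        alpha = control$alpha, beta = control$beta,
                        extra = one_hot(train$patients$treatment, vocab,
                                        "treatment"),
                        seed = seed, control = control)
    feats_va <- cbind(apply_normalizer(comb_va, norm, clip = TRUE),
                      one_hot(val$patients$treatment, vocab, "treatment"))
    pr <- predict(model, feats_va)
    pred <- tibble(patient_id = val$patients$patient_id,
                   treatment = val$patients$treatment,
                   score = pr$score, class = pr$class)
    selection <- list(combined = model$selection)
    threshold <- as.numeric(model$threshold)
    sim <- NULL
  }
  list(
    scores = tibble(patient_id = pred$patient_id, fold = fold,
                    treatment = val$patients$treatment, ts = ts_va,
                    score = pred$score, class = pred$class,
                    threshold = threshold),
    selection = selection, model = model, simulation = sim)
}

#' @export
print.mult_cv <- function(x, ...) {
  cat("<mult_cv> pipeline ", x$pipeline, ", ",
      nrow(x$scores), " validation patients over ",
      length(unique(x$scores$fold)), " folds\n", sep = "")
  print(x$metrics$pooled)
  if (length(x$failures) > 0) {
    cat("failures:\n "); cat(x$failures, sep = "\n ")
  }
  invisible(x)
}

#' @rdname run_cv
#' @param x A `mult_cv`.
#' @param ... Unused.
#' @export
tidy.mult_cv <- function(x, ...) x$metrics$per_fold

#' @rdname run_cv
#' @export
glance.mult_cv <- function(x, ...) {
  bind_cols(tibble(pipeline = x$pipeline), x$metrics$pooled,
            tibble(mean_fold_auc = mean(x$metrics$per_fold$auc),
                   sd_fold_auc = sd(x$metrics$per_fold$auc),
                   n_failed_folds = length(x$failures)))
}

#' @rdname run_cv
#' @param object A `mult_cv`.
#' @export
autoplot.mult_cv <- function(object, ...) {
  ggplot(object$metrics$per_fold,
         aes(x = factor(.data$fold), y = .data$auc)) +
    geom_col(fill = "steelblue") +
    labs(x = "fold", y = "validation AUC",
         title = paste0(object$pipeline, ": per-fold validation AUC")) +
    theme_minimal()
}

#' Compare two pipelines' per-fold AUCs with a t-test
#'
#' Two-sample t-test over the matched per-fold validation AUC vectors of
#' two cross-validation runs that used the same plan.
#'
#' @param aucs_a,aucs_b Equal-length numeric vectors of per-fold AUCs.
#' @return The t-test p-value.
#' @export
paired_auc_test <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b)) abort("fold AUC vectors differ in length")
  if (length(aucs_a) < 2) abort("need at least two folds")
  if (sd(aucs_a) == 0 && sd(aucs_b) == 0) {
    return(if (isTRUE(all.equal(mean(aucs_a), mean(aucs_b)))) 1 else 0)
  }
  t.test(aucs_a, aucs_b)$p.value
}

#' Marker-relationship graph across cross-validation rounds
#'
#' Undirected graph over every marker selected in at least one CV round.
#' Node attributes: `size` (number of rounds selected), `role`
#' (clinical vs gene, drawn as different shapes), `mean_p` (mean KS
#' p-value across the rounds where the marker was scored; color intensity
#' should be drawn inversely proportional to it).  An edge connects two
#' markers co-selected in at least one round, with `width` = the number
#' of rounds both were selected; zero-width edges are omitted.
#'
#' @param selection_reports List with one element per CV round; each
#'   element is a [select_markers()] report or a list of them (e.g. the
#'   clinical and gene reports of one round).
#' @return An [igraph::graph] with the attributes above.
#' @export
build_marker_graph <- function(selection_reports) {
  if (length(selection_reports) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  per_round <- map(selection_reports, function(rep) {
    if (inherits(rep, "mult_selection")) rep <- list(rep)
    bind_rows(map(rep, as_tibble))
  })
  sel_sets <- map(per_round, ~ .x$marker[.x$status == "selected"])
  all_rows <- bind_rows(per_round)
  nodes <- all_rows |>
    filter(.data$marker %in% unlist(sel_sets)) |>
    group_by(marker = .data$marker) |>
    summarise(role = .data$role[1], mean_p = mean(.data$p_value),
              .groups = "drop") |>
    left_join(tibble(marker = unlist(sel_sets)) |> count(.data$marker),
              by = "marker") |>
    rename(size = "n")
  if (nrow(nodes) == 0) return(igraph::make_empty_graph(directed = FALSE))

  pairs <- list()
  for (s in sel_sets) {
    if (length(s) < 2) next
    cmb <- utils::combn(sort(s), 2)
    pairs[[length(pairs) + 1]] <- tibble(from = cmb[1, ], to = cmb[2, ])
  }
  edges <- if (length(pairs) > 0) {
    bind_rows(pairs) |> count(.data$from, .data$to, name = "width")
  } else {
    tibble(from = character(), to = character(), width = integer())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = as.data.frame(nodes))
}
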