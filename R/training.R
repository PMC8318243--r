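#' Binary cross-entropy (log loss)
#'
#' `-(1/N) sum(y log(yhat) + (1 - y) log(1 - yhat))`, with predictions
#' epsilon-clipped away from 0 and 1 for numerical safety.
#'
#' @param y Binary 0/1 vector.
#' @param y_hat Predicted probabilities, same length.
#' @param eps Clipping bound.
#' @return The mean log loss.
#' @export
log_loss <- function(y, y_hat, eps = 1e-15) {
  if (length(y) != length(y_hat)) abort("y and y_hat lengths differ")
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training-data decision threshold (Youden's J)
#'
#' Scans every midpoint between adjacent sorted unique scores and returns
#' the threshold maximizing sensitivity + specificity (Youden's J) on the
#' supplied training scores; a score at or above the threshold is called
#' sensitive.  Ties go to the lower threshold.  When all scores are equal
#' the common value itself is returned (J = 0).
#'
#' @param scores Predicted probabilities.
#' @param labels Binary 0/1 vector (both classes present).
#' @return The threshold, with the achieved J in attribute `youden_j`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes are required to choose a threshold")
  }
  u <- sort(unique(scores))
  if (length(u) == 1) return(structure(u, youden_j = 0))
  cands <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cands, function(thr) {
    pred <- scores >= thr
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  best <- which.max(j)   # first max = lowest threshold on ties
  structure(cands[best], youden_j = j[best])
}

#' Pipeline tuning knobs
#'
#' Collects every tunable compute setting of the training pipeline in one
#' object: selection thresholds, Bayesian-optimization budget, boosting
#' rounds and early stopping, cluster-count search settings, and the
#' denoiser budget.  The defaults are the published settings; smaller
#' budgets are useful for quick runs and are what the examples use.
#'
#' @param alpha KS significance level for marker selection.
#' @param beta Absolute-correlation redundancy threshold.
#' @param bo_init,bo_iter Random / surrogate-guided evaluations of the
#'   Bayesian optimizer.
#' @param nrounds Maximum boosting iterations.
#' @param early_stopping Boosting iterations without log-loss improvement
#'   tolerated before stopping.
#' @param ncs_stall,ncs_cmax,ncs_nstart Cluster-count search: stall
#'   length, optional count cap, k-means restarts.
#' @param denoise_patience,denoise_max_epochs,denoise_l2 Denoiser budget
#'   and L2 scale.
#' @return A `mult_control` list.
#' @export
mult_control <- function(alpha = 0.05, beta = 0.75,
                         bo_init = 10, bo_iter = 50,
                         nrounds = 100, early_stopping = 1,
                         ncs_stall = 10, ncs_cmax = NULL, ncs_nstart = 10,
                         denoise_patience = 1000, denoise_max_epochs = 5000,
                         denoise_l2 = 0.01) {
  structure(as.list(environment()), class = "mult_control")
}

## ---- classifier backends ------------------------------------------------

# Map the boosted-tree hyperparameter names onto xgboost's leaf-wise
# (lossguide) growth.  min_child_samples and bin_construct_sample_cnt have
# no xgboost counterpart; they are carried in H but inert.
gbt_params <- function(h, seed) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       tree_method = "hist", grow_policy = "lossguide", max_depth = 0,
       max_leaves = as.integer(h$num_leaves),
       scale_pos_weight = h$scale_pos_weight,
       max_bin = as.integer(h$max_bin),
       min_child_weight = h$min_sum_hessian_in_leaf,
       subsample = h$bagging_fraction,
       colsample_bytree = h$feature_fraction,
       colsample_bynode = h$feature_fraction_bynode,
       nthread = 1, seed = as.integer(seed) %% 100000L)
}

fit_gbt <- function(x, y, h, nrounds, seed, eval_x = NULL, eval_y = NULL,
                    early_stopping = NULL) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  args <- list(params = gbt_params(h, seed), data = dtrain,
               nrounds = nrounds, verbose = 0)
  if (!is.null(eval_x)) {
    args$evals <- list(val = xgboost::xgb.DMatrix(eval_x, label = eval_y))
    args$early_stopping_rounds <- early_stopping
  }
  do.call(xgboost::xgb.train, args)
}

predict_gbt <- function(booster, x) {
  predict(booster, x)
}

gbt_val_loss <- function(booster) {
  log <- attributes(booster)$evaluation_log
  min(log$val_logloss)
}

fit_backend <- function(model, x, y, h, seed, control) {
  switch(model,
    gbt = fit_gbt(x, y, h, nrounds = control$nrounds, seed = seed),
    mlp = with_seed(seed,
      nnet::nnet(x, y, size = as.integer(h$hidden_layer_sizes),
                 maxit = as.integer(h$max_iter), reltol = h$tol,
                 decay = 1e-4, entropy = TRUE, trace = FALSE,
                 MaxNWts = 100000)),
    svm = with_seed(seed,
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = h$kernel,
                 cost = h$C, gamma = h$gamma, degree = as.integer(h$degree),
                 probability = TRUE, scale = FALSE)))
}

predict_backend <- function(model, fit, x) {
  switch(model,
    gbt = predict_gbt(fit, x),
    mlp = as.numeric(predict(fit, x, type = "raw")),
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    })
}

## ---- TSPT ---------------------------------------------------------------

split_retry <- function(y, n_folds, seed, max_attempts = 5) {
  for (a in seq_len(max_attempts)) {
    folds <- stratified_folds(y, n_folds, derive_seed(seed, paste0("a", a)))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(y[folds == f])) == 2
    }, logical(1)))
    if (ok) return(folds)
  }
  abort(paste0("could not build ", n_folds,
               " folds with both classes after ", max_attempts, " attempts"))
}

#' Train the treatment-sensitivity predictor ensemble
#'
#' The supervised head of the pipeline.  Phase 1 tunes the boosted-tree
#' hyperparameters with [bayesian_optimize()] using half of the training
#' data: one stratified half trains, the other yields the validation log
#' loss.  Phase 2 splits the training data into three stratified folds
#' and trains one model per pairwise fold union (three models), each with
#' early stopping on the held-out third (stop after `early_stopping`
#' boosting iterations without log-loss improvement, or at `nrounds`).
#' The ensemble TS score is the arithmetic mean of the three member
#' scores; the decision threshold is chosen on the training scores with
#' [select_threshold()].
#'
#' @param features Data frame (optionally with `patient_id`) or numeric
#'   matrix of normalized, aligned features (the concatenation of the
#'   selected-gene, selected-clinical, profiling, gene-cluster, denoised
#'   and treatment blocks).
#' @param labels Binary 0/1 sensitivity outcome (both classes present).
#' @param seed Integer seed.
#' @param control A [mult_control()].
#' @return A `mult_tspt`: `members` (three boosters), `best_h`, `bo`
#'   (optimization trace), `threshold`, `feature_names`.
#' @export
train_tspt <- function(features, labels, seed = 1,
                       control = mult_control()) {
  x <- df_to_matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("both classes must be present")

  half <- split_retry(y, 2, derive_seed(seed, "bo_split"))
  objective <- function(h) {
    m <- fit_gbt(x[half == 1, , drop = FALSE], y[half == 1], h,
                 nrounds = control$nrounds, seed = seed,
                 eval_x = x[half == 2, , drop = FALSE],
                 eval_y = y[half == 2],
                 early_stopping = control$early_stopping)
    gbt_val_loss(m)
  }
  bo <- bayesian_optimize(hp_space("gbt"), objective,
                          n_init = control$bo_init,
                          n_iter = control$bo_iter,
                          seed = derive_seed(seed, "bo"))

  thirds <- split_retry(y, 3, derive_seed(seed, "tspt_split"))
  members <- map(1:3, function(f) {
    tr <- thirds != f
    fit_gbt(x[tr, , drop = FALSE], y[tr], bo$best,
            nrounds = control$nrounds, seed = derive_seed(seed, paste0("m", f)),
            eval_x = x[!tr, , drop = FALSE], eval_y = y[!tr],
            early_stopping = control$early_stopping)
  })
  obj <- structure(
    list(members = members, best_h = bo$best, bo = bo,
         feature_names = colnames(x), threshold = NA_real_),
    class = "mult_tspt")
  train_scores <- predict(obj, x)$score
  obj$threshold <- select_threshold(train_scores, y)
  obj
}

#' @rdname train_tspt
#' @param object A `mult_tspt`.
#' @param newdata Feature table with exactly the training feature columns.
#' @param ... Unused.
#' @return For `predict`: tibble with `score` (mean of the three member
#'   scores, in `[0, 1]`) and `class` (1 iff `score >= threshold`).
#' @export
predict.mult_tspt <- function(object, newdata, ...) {
  x <- df_to_matrix(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    abort("feature columns do not match the trained feature layout")
  }
  scores <- rowMeans(vapply(object$members, predict_gbt, numeric(nrow(x)),
                            x = x))
  tibble(score = scores,
         class = if (is.na(object$threshold[1])) NA_integer_ else
           as.integer(scores >= as.numeric(object$threshold)))
}

#' @rdname train_tspt
#' @param x A `mult_tspt`.
#' @export
glance.mult_tspt <- function(x, ...) {
  tibble(n_features = length(x$feature_names),
         bo_evaluations = nrow(x$bo$trace),
         bo_best_loss = x$bo$best_loss,
         threshold = as.numeric(x$threshold),
         youden_j = attr(x$threshold, "youden_j"))
}

## ---- SMLA ---------------------------------------------------------------

#' Train the simplified baseline pipeline (SMLA)
#'
#' Three steps: marker selection with [select_markers()], Bayesian
#' hyperparameter optimization of the chosen classifier (one stratified
#' half of the training data trains each candidate, the other half yields
#' the log loss), then a final classifier fit on all training data with
#' the optimized hyperparameters.  The decision threshold follows the
#' same training-data Youden rule as the full pipeline.
#'
#' @param features Data frame or matrix of normalized marker values; the
#'   selection step runs on these columns.
#' @param labels Binary 0/1 outcome (a sensitivity class or a FISH call).
#' @param model Classifier family: `"gbt"`, `"mlp"` or `"svm"`.
#' @param alpha,beta Selection thresholds (see [select_markers()]).
#' @param extra Optional data frame/matrix of columns appended after
#'   selection (e.g. the one-hot treatment block), exempt from selection.
#' @param seed Integer seed.
#' @param control A [mult_control()].
#' @return A `mult_smla`: `selection`, `model`, `fit`, `best_h`, `bo`,
#'   `threshold`, `feature_names`.
#' @export
train_smla <- function(features, labels, model = c("gbt", "mlp", "svm"),
                       alpha = 0.05, beta = 0.75, extra = NULL, seed = 1,
                       control = mult_control()) {
  model <- match.arg(model)
  y <- as.integer(labels)
  sel <- select_markers(features, y, alpha = alpha, beta = beta)
  keep <- selected_markers(sel)
  if (length(keep) == 0) {
    abort("no markers selected; consider a larger alpha")
  }
  x <- df_to_matrix(features)[, keep, drop = FALSE]
  if (!is.null(extra)) x <- cbind(x, df_to_matrix(extra))

  half <- split_retry(y, 2, derive_seed(seed, "smla_split"))
  x1 <- x[half == 1, , drop = FALSE]; y1 <- y[half == 1]
  x2 <- x[half == 2, , drop = FALSE]; y2 <- y[half == 2]
  objective <- function(h) {
    if (model == "gbt") {
      m <- fit_gbt(x1, y1, h, nrounds = control$nrounds, seed = seed,
                   eval_x = x2, eval_y = y2,
                   early_stopping = control$early_stopping)
      gbt_val_loss(m)
    } else {
      fit <- fit_backend(model, x1, y1, h, seed, control)
      log_loss(y2, predict_backend(model, fit, x2))
    }
  }
  bo <- bayesian_optimize(hp_space(model), objective,
                          n_init = control$bo_init,
                          n_iter = control$bo_iter,
                          seed = derive_seed(seed, "smla_bo"))
  fit <- fit_backend(model, x, y, bo$best, derive_seed(seed, "smla_fit"),
                     control)
  obj <- structure(
    list(selection = sel, model = model, fit = fit, best_h = bo$best,
         bo = bo, feature_names = colnames(x), threshold = NA_real_),
    class = "mult_smla")
  obj$threshold <- select_threshold(predict(obj, x)$score, y)
  obj
}

#' @rdname train_smla
#' @param object A `mult_smla`.
#' @param newdata Feature table containing at least the training columns
#'   (selected markers plus any `extra` columns).
#' @param ... Unused.
#' @export
predict.mult_smla <- function(object, newdata, ...) {
  x <- df_to_matrix(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature column(s): ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  x <- x[, object$feature_names, drop = FALSE]
  scores <- predict_backend(object$model, object$fit, x)
  tibble(score = scores,
         class = if (is.na(object$threshold[1])) NA_integer_ else
           as.integer(scores >= as.numeric(object$threshold)))
}

#' @rdname train_smla
#' @param x A `mult_smla`.
#' @export
glance.mult_smla <- function(x, ...) {
  tibble(model = x$model,
         n_selected = sum(x$selection$status == "selected"),
         bo_best_loss = x$bo$best_loss,
         threshold = as.numeric(x$threshold))
}
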