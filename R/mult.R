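#' Train the full multi-learning pipeline on a training cohort
#'
#' Runs every training stage on the supplied cohort and nothing else, so a
#' held-out validation set never influences any fitted component:
#'
#' 1. min-max normalization of clinical markers and gene expression
#'    (bounds learned here, clipped at prediction time);
#' 2. clinical-marker selection and gene selection with
#'    [select_markers()];
#' 3. genetic profiling (patient-to-centroid distances, cluster count via
#'    [select_num_clusters()]), gene clustering (per-cluster mean
#'    expression, count via NCS on the transposed matrix) and gene
#'    denoising ([train_denoiser()]) over the selected genes;
#' 4. min-max normalization of the extracted blocks;
#' 5. the boosted-tree ensemble head [train_tspt()] on the concatenation
#'    of selected genes, selected clinical markers, profiling distances,
#'    gene-cluster means, denoised genes and the one-hot treatment block.
#'
#' Degenerate selections degrade gracefully: the profiling and clustering
#' branches need at least 2 selected genes and the denoiser at least 4;
#' blocks that cannot be built are skipped.
#'
#' @param cohort A complete [mult_cohort()] (training patients only).
#' @param ts Binary sensitivity outcome aligned with the cohort; defaults
#'   to deriving it from the response classes with [ts_definition()]
#'   (`ts_def`).
#' @param ts_def The [ts_definition()] used when `ts` is `NULL`.
#' @param treatments Treatment vocabulary for the one-hot block; defaults
#'   to the treatments observed in the cohort.
#' @param seed Integer seed; all stage seeds derive from it.
#' @param control A [mult_control()].
#' @return A `mult_model` holding every fitted component plus the
#'   decision threshold.
#' @export
train_mult <- function(cohort, ts = NULL, ts_def = ts_definition("CR"),
                       treatments = NULL, seed = 1,
                       control = mult_control()) {
  if (is.null(ts)) ts <- derive_ts(cohort$patients$response, ts_def)
  ts <- as.integer(ts)
  if (anyNA(ts)) abort("sensitivity outcome contains missing values")
  treatments <- treatments %||% sort(unique(cohort$patients$treatment))

  clin <- df_to_matrix(cohort$clinical)
  expr <- df_to_matrix(cohort$expression)
  if (anyNA(clin)) {
    abort("clinical markers contain missing values; run filter_cohort() first")
  }
  norm_clin <- fit_normalizer(clin)
  norm_expr <- fit_normalizer(expr)
  clin_n <- apply_normalizer(clin, norm_clin)
  expr_n <- apply_normalizer(expr, norm_expr)

  sel_clin <- select_markers(clin_n, ts, alpha = control$alpha,
                             beta = control$beta, role = "clinical")
  sel_gene <- select_markers(expr_n, ts, alpha = control$alpha,
                             beta = control$beta, role = "gene")
  genes <- selected_markers(sel_gene)
  clins <- selected_markers(sel_clin)
  if (length(genes) == 0 && length(clins) == 0) {
    warn("no markers selected; the model will use treatment alone")
  }

  g_prime <- expr_n[, genes, drop = FALSE]
  profiling <- NULL
  gene_clusters <- NULL
  denoiser <- NULL
  if (length(genes) >= 2 && nrow(g_prime) >= 3) {
    o <- select_num_clusters(g_prime, max_stall = control$ncs_stall,
                             c_max = control$ncs_cmax,
                             nstart = control$ncs_nstart,
                             seed = derive_seed(seed, "ncs_gp"))
    profiling <- genetic_profiling(g_prime, o$count,
                                   nstart = control$ncs_nstart,
                                   seed = derive_seed(seed, "gp"))
    profiling$ncs <- o
    if (length(genes) >= 3) {
      k <- select_num_clusters(t(g_prime), max_stall = control$ncs_stall,
                               c_max = control$ncs_cmax,
                               nstart = control$ncs_nstart,
                               seed = derive_seed(seed, "ncs_gc"))
      gene_clusters <- gene_clustering(g_prime, k$count,
                                       nstart = control$ncs_nstart,
                                       seed = derive_seed(seed, "gc"))
      gene_clusters$ncs <- k
    }
    if (length(genes) >= 4) {
      denoiser <- train_denoiser(
        g_prime, patience = control$denoise_patience,
        max_epochs = control$denoise_max_epochs,
        l2_scale = control$denoise_l2,
        seed = derive_seed(seed, "gd"))
    }
  }

  model <- structure(
    list(norm_clin = norm_clin, norm_expr = norm_expr,
         sel_clin = sel_clin, sel_gene = sel_gene,
         profiling = profiling, gene_clusters = gene_clusters,
         denoiser = denoiser, norm_extracted = NULL,
         treatments = treatments, tspt = NULL, control = control,
         seed = seed),
    class = "mult_model")

  raw_ext <- extract_blocks(model, clin, expr, clip = FALSE)
  if (!is.null(raw_ext$extracted)) {
    model$norm_extracted <- fit_normalizer(raw_ext$extracted)
  }
  features <- assemble_features(model, clin, expr,
                                cohort$patients$treatment, clip = FALSE)
  model$tspt <- train_tspt(features, ts,
                           seed = derive_seed(seed, "tspt"),
                           control = control)
  model
}

# core blocks (selected genes/clinical + raw extracted blocks) for a set of
# patients; `clip` governs the min-max transform of the raw marker blocks
extract_blocks <- function(model, clin, expr, clip) {
  clin_n <- apply_normalizer(clin, model$norm_clin, clip = clip)
  expr_n <- apply_normalizer(expr, model$norm_expr, clip = clip)
  g_prime <- expr_n[, selected_markers(model$sel_gene), drop = FALSE]
  c_prime <- clin_n[, selected_markers(model$sel_clin), drop = FALSE]
  blocks <- list()
  if (!is.null(model$profiling)) {
    blocks$L <- predict(model$profiling, g_prime)
  }
  if (!is.null(model$gene_clusters)) {
    blocks$E <- predict(model$gene_clusters, g_prime)
  }
  if (!is.null(model$denoiser)) {
    blocks$Gd <- denoise(model$denoiser, g_prime)
  }
  extracted <- if (length(blocks) > 0) do.call(cbind, unname(blocks)) else NULL
  list(g_prime = g_prime, c_prime = c_prime, extracted = extracted)
}

assemble_features <- function(model, clin, expr, treatment, clip) {
  bl <- extract_blocks(model, clin, expr, clip = clip)
  ext <- NULL
  if (!is.null(bl$extracted)) {
    ext <- apply_normalizer(bl$extracted, model$norm_extracted, clip = clip)
  }
  tmat <- one_hot(treatment, model$treatments, "treatment")
  cbind(bl$g_prime, bl$c_prime, ext, tmat)
}

#' @rdname train_mult
#' @param object A `mult_model`.
#' @param cohort A [mult_cohort()] of patients to score (its clinical and
#'   expression tables must carry the training marker columns).
#' @param treatment Optional treatment override: a single treatment name
#'   applied to every patient, or one per patient.  Defaults to each
#'   patient's actual treatment.
#' @param ... Unused.
#' @return For `predict`: tibble with `patient_id`, `treatment`, `score`
#'   and `class`.
#' @export
predict.mult_model <- function(object, cohort, treatment = NULL, ...) {
  trt <- treatment %||% cohort$patients$treatment
  if (length(trt) == 1) trt <- rep(trt, n_patients(cohort))
  features <- assemble_features(object, df_to_matrix(cohort$clinical),
                                df_to_matrix(cohort$expression),
                                trt, clip = TRUE)
  pred <- predict(object$tspt, features)
  tibble(patient_id = cohort$patients$patient_id, treatment = trt,
         score = pred$score, class = pred$class)
}

#' @export
print.mult_model <- function(x, ...) {
  cat("<mult_model>\n")
  cat("  selected genes: ", length(selected_markers(x$sel_gene)),
      ", clinical markers: ", length(selected_markers(x$sel_clin)), "\n",
      sep = "")
  if (!is.null(x$profiling)) {
    cat("  patient clusters (profiling): ", x$profiling$o, "\n", sep = "")
  }
  if (!is.null(x$gene_clusters)) {
    cat("  gene clusters: ", x$gene_clusters$k, "\n", sep = "")
  }
  if (!is.null(x$denoiser)) {
    cat("  denoiser widths: [", paste(x$denoiser$widths, collapse = ", "),
        "]\n", sep = "")
  }
  cat("  treatments: ", paste(x$treatments, collapse = ", "), "\n", sep = "")
  cat("  decision threshold: ", signif(as.numeric(x$tspt$threshold), 4),
      "\n", sep = "")
  invisible(x)
}

#' @rdname train_mult
#' @param x A `mult_model`.
#' @export
glance.mult_model <- function(x, ...) {
  tibble(
    n_genes_selected = length(selected_markers(x$sel_gene)),
    n_clinical_selected = length(selected_markers(x$sel_clin)),
    o_patient_clusters = if (is.null(x$profiling)) NA_integer_ else
      as.integer(x$profiling$o),
    k_gene_clusters = if (is.null(x$gene_clusters)) NA_integer_ else
      as.integer(x$gene_clusters$k),
    denoiser_best_mse = if (is.null(x$denoiser)) NA_real_ else
      x$denoiser$best_mse,
    bo_best_loss = x$tspt$bo$best_loss,
    threshold = as.numeric(x$tspt$threshold))
}
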