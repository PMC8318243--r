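## Internal helpers shared across stages.

# Derive a reproducible 32-bit child seed from a master seed and a stage
# label, so every stochastic stage can be replayed independently.
derive_seed <- function(seed, label) {
  codes <- as.numeric(utf8ToInt(label))
  h <- (sum(codes * seq_along(codes)) * 2654435) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# data frame (optionally with an id column) -> numeric matrix with rownames
df_to_matrix <- function(df, id_col = "patient_id") {
  if (is.matrix(df)) {
    storage.mode(df) <- "double"
    return(df)
  }
  df <- as.data.frame(df)
  ids <- NULL
  if (!is.null(id_col) && id_col %in% names(df)) {
    ids <- as.character(df[[id_col]])
    df <- df[setdiff(names(df), id_col)]
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric feature column(s): ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(ids)) rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, id_col = "patient_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  if (!is.null(rownames(m))) {
    out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  }
  out
}

# Pearson correlation defined as 0 when either vector is constant.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# population standard deviation (divide by n)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# one-hot encode a character/factor vector against a fixed vocabulary
one_hot <- function(x, vocab, prefix) {
  x <- as.character(x)
  unknown <- setdiff(unique(x), vocab)
  if (length(unknown) > 0) {
    abort(paste0("value(s) outside vocabulary: ", paste(unknown, collapse = ", ")))
  }
  m <- vapply(vocab, function(v) as.double(x == v), numeric(length(x)))
  m <- matrix(m, nrow = length(x),
              dimnames = list(NULL, paste0(prefix, "=", vocab)))
  m
}

# Mann-Whitney rank formulation of the AUC (exact, handles ties by midranks)
auc_mw <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# confusion metrics at a hard threshold (predicted positive iff score >= thr)
confusion_metrics <- function(labels, scores, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tibble(
    n = length(labels),
    auc = auc_mw(labels, scores),
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# stratified assignment of 1..n into n_folds, balanced within each stratum
stratified_folds <- function(strata, n_folds, seed) {
  folds <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}
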