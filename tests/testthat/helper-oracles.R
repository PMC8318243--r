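# Independent reference implementations used as oracles.  These replay the
# published procedures naively (plain loops, no caching, separate code
# paths) so agreement with the package is informative.

# Literal replay of the marker-selection pseudocode: markers processed in
# ascending p-value order (ties by name), excluded markers skipped as
# anchors and partners, anchor exclusion ends its own comparison loop.
oracle_select_markers <- function(m, outcome, alpha, beta) {
  p <- vapply(colnames(m), function(M) {
    suppressWarnings(
      stats::ks.test(m[outcome == 0, M], m[outcome == 1, M])$p.value)
  }, numeric(1))
  marker_set <- colnames(m)[order(p, colnames(m))]
  excluded <- character(0)
  analysed <- character(0)
  for (m1 in marker_set) {
    if (m1 %in% excluded) next
    analysed <- union(analysed, m1)
    if (p[m1] > alpha) {
      excluded <- union(excluded, m1)
    } else {
      for (m2 in setdiff(marker_set, analysed)) {
        if (m2 %in% excluded) next
        if (p[m2] > alpha) {
          excluded <- union(excluded, m2)
        } else {
          r <- stats::cor(m[, m1], m[, m2])
          pc <- if (is.na(r)) 0 else abs(r)
          if (pc > beta) {
            if (p[m2] >= p[m1]) {
              excluded <- union(excluded, m2)
            } else {
              excluded <- union(excluded, m1)
              break
            }
          }
        }
      }
    }
  }
  setdiff(marker_set, excluded)
}

# random selection instance: a few informative markers, exact-duplicate
# redundancy, the rest null
random_selection_instance <- function(n = 60, g = 15, seed = 1) {
  withr::with_seed(seed, {
    outcome <- rbinom(n, 1, 0.5)
    if (length(unique(outcome)) < 2) outcome[1:2] <- c(0L, 1L)
    m <- matrix(rnorm(n * g), n, g,
                dimnames = list(NULL, sprintf("m%02d", seq_len(g))))
    n_inf <- sample(1:4, 1)
    for (j in seq_len(n_inf)) m[, j] <- m[, j] + outcome
    # one noisy duplicate of an informative marker, one of a null marker
    m[, n_inf + 1] <- m[, 1] + rnorm(n, sd = 0.05)
    m[, g] <- m[, g - 1] + rnorm(n, sd = 0.05)
    list(m = m, outcome = outcome)
  })
}

# exhaustive-scan threshold oracle over midpoints of sorted unique scores
oracle_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cands <- (u[-1] + u[-length(u)]) / 2
  best_j <- -Inf
  best_t <- NA_real_
  for (thr in cands) {
    pred <- as.integer(scores >= thr)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    if (sens + spec - 1 > best_j) {
      best_j <- sens + spec - 1
      best_t <- thr
    }
  }
  best_t
}

# exact small-sample KS null: enumerate all label assignments of the
# pooled sample and compute P(D >= observed)
oracle_ks_exact_p <- function(x, y) {
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  }
  obs <- ks_stat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  stats_all <- apply(idx, 2, function(ii) {
    ks_stat(pooled[ii], pooled[-ii])
  })
  mean(stats_all >= obs - 1e-12)
}

# three-gaussian-blob data for cluster-count recovery
blob_data <- function(n_per = 50, k = 3, sep = 10, sd = 1, d = 2, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d) * 0
    for (j in seq_len(k)) centers[j, 1] <- (j - 1) * sep
    if (d > 1 && k > 2) centers[, 2] <- ((seq_len(k) %% 2) * sep)
    do.call(rbind, lapply(seq_len(k), function(j) {
      sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[j, ], "+")
    }))
  })
}

# standard small planted-signal cohort used across tests
test_cohort <- function(n = 200, genes = 80, informative = 6, seed = 1, ...) {
  filter_cohort(generate_cohort(synth_config(
    n_patients = n, n_genes = genes, n_informative_genes = informative,
    seed = seed, ...)))
}

# a light control so model-fitting tests stay quick
quick_control <- function(...) {
  mult_control(bo_init = 3, bo_iter = 3, denoise_patience = 30,
               denoise_max_epochs = 150, ncs_cmax = 6, ncs_nstart = 3, ...)
}
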