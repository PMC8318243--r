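#' Silhouette-coefficient-based metric (SCM)
#'
#' The cluster-count score maximized by [select_num_clusters()]:
#' `(mean(SC) - sd(SC)) / (sd(cluster sizes) + 1)`, where SC are the
#' per-sample silhouette coefficients.  Both standard deviations are
#' population standard deviations (divide by n).  Rewarding a high mean
#' silhouette while penalizing silhouette spread and cluster-size
#' imbalance; it reduces to the mean silhouette when silhouettes are
#' constant and cluster sizes are equal.
#'
#' @param cluster_labels Integer cluster assignment per sample (at least
#'   two distinct clusters).
#' @param silhouette_values One silhouette coefficient per sample.
#' @return The SCM value.
#' @export
scm <- function(cluster_labels, silhouette_values) {
  if (length(cluster_labels) != length(silhouette_values)) {
    abort("one silhouette value per sample is required")
  }
  sizes <- as.numeric(table(cluster_labels))
  if (length(sizes) < 2) {
    abort("SCM requires at least two clusters (silhouette undefined)")
  }
  (mean(silhouette_values) - sd_pop(silhouette_values)) / (sd_pop(sizes) + 1)
}

#' Choose the number of k-means clusters by maximizing the SCM
#'
#' Iterates candidate counts `c = c_start, c_start + 1, ...`, fitting
#' k-means (k-means++-style multiple restarts) and scoring each fit with
#' [scm()].  The scan stops after `max_stall` consecutive counts without a
#' new maximum, or when a count becomes infeasible (more clusters than
#' distinct samples).  The returned count is the arg-max of the recorded
#' trace; ties go to the smallest count.
#'
#' @param x Data frame or numeric matrix, samples in rows.
#' @param max_stall Consecutive non-improving counts before stopping.
#' @param c_start First candidate count.
#' @param c_max Optional hard upper bound on the candidate count.
#' @param nstart Random restarts per k-means fit.
#' @param seed Integer seed (fixes the k-means restarts).
#' @return An `ncs_result`: list with `count` and `trace` (tibble of
#'   `c`, `scm`).
#' @export
select_num_clusters <- function(x, max_stall = 10, c_start = 2,
                                c_max = NULL, nstart = 10, seed = 1) {
  m <- df_to_matrix(x)
  n <- nrow(m)
  if (n < c_start + 1) abort("need at least c_start + 1 samples")
  n_distinct_rows <- nrow(unique(m))
  hi <- min(c_max %||% Inf, n_distinct_rows - 1, n - 1)
  dmat <- stats::dist(m)
  trace <- list()
  best <- -Inf
  stall <- 0
  with_seed(seed, {
    for (cc in seq(c_start, max(c_start, hi))) {
      km <- tryCatch(kmeans(m, centers = cc, nstart = nstart, iter.max = 50),
                     error = function(e) NULL)
      if (is.null(km)) break
      sil <- cluster::silhouette(km$cluster, dmat)
      val <- scm(km$cluster, sil[, "sil_width"])
      trace[[length(trace) + 1]] <- tibble(c = cc, scm = val)
      if (val > best) {
        best <- val
        stall <- 0
      } else {
        stall <- stall + 1
      }
      if (stall >= max_stall) break
    }
  })
  if (length(trace) == 0) abort("no feasible cluster count")
  trace <- bind_rows(trace)
  structure(list(count = trace$c[which.max(trace$scm)], trace = trace),
            class = "ncs_result")
}

#' @export
print.ncs_result <- function(x, ...) {
  cat("<ncs_result> chosen count:", x$count, "over",
      nrow(x$trace), "candidates\n")
  invisible(x)
}

#' @rdname select_num_clusters
#' @param x An `ncs_result`.
#' @param ... Unused.
#' @export
tidy.ncs_result <- function(x, ...) x$trace

#' @rdname select_num_clusters
#' @param object An `ncs_result`.
#' @export
autoplot.ncs_result <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$c, y = .data$scm)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = object$count, linetype = "dashed") +
    labs(x = "number of clusters", y = "SCM",
         title = paste0("Cluster-count selection (chosen: ", object$count, ")")) +
    theme_minimal()
}

#' Genetic profiling: patient distances to k-means centroids
#'
#' Clusters patients in selected-gene space with k-means and represents
#' each patient by the Euclidean distances to the `o` cluster centroids.
#' Centroids are persisted so validation patients are projected without
#' refitting.
#'
#' @param g_prime Data frame or matrix, patients x selected genes
#'   (normalized).
#' @param o Number of patient clusters (from [select_num_clusters()]).
#' @param nstart Random k-means restarts.
#' @param seed Integer seed.
#' @return A `mult_profiling` model; its `distances` element is the
#'   training-set patients x `o` distance matrix `L`.
#' @export
genetic_profiling <- function(g_prime, o, nstart = 10, seed = 1) {
  m <- df_to_matrix(g_prime)
  km <- with_seed(seed, kmeans(m, centers = o, nstart = nstart,
                               iter.max = 50))
  model <- structure(
    list(centroids = km$centers, genes = colnames(m), o = o),
    class = "mult_profiling")
  model$distances <- predict(model, m)
  model
}

#' @rdname genetic_profiling
#' @param object A `mult_profiling` model.
#' @param newdata Patients x genes table over the training gene set.
#' @param ... Unused.
#' @return For `predict`: patients x `o` matrix of centroid distances.
#' @export
predict.mult_profiling <- function(object, newdata, ...) {
  m <- df_to_matrix(newdata)
  if (!identical(colnames(m), object$genes)) {
    abort("gene set does not match the profiling training gene set")
  }
  out <- vapply(seq_len(object$o), function(j) {
    sqrt(rowSums(sweep(m, 2, object$centroids[j, ], "-")^2))
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m),
                                paste0("L_centroid", seq_len(object$o))))
  out
}

#' Gene clustering: per-cluster mean expression features
#'
#' Clusters the selected genes (k-means on the transposed expression
#' matrix, genes as samples) and represents each patient by the mean
#' expression over each gene cluster.  Cluster assignments are persisted
#' so validation patients reuse the training clustering.
#'
#' @param g_prime Data frame or matrix, patients x selected genes
#'   (normalized; transposed internally).
#' @param k Number of gene clusters (from [select_num_clusters()] on the
#'   transposed matrix).
#' @param nstart Random k-means restarts.
#' @param seed Integer seed.
#' @return A `mult_gene_clusters` model; its `means` element is the
#'   training-set patients x `k` matrix `E`.
#' @export
gene_clustering <- function(g_prime, k, nstart = 10, seed = 1) {
  m <- df_to_matrix(g_prime)
  km <- with_seed(seed, kmeans(t(m), centers = k, nstart = nstart,
                               iter.max = 50))
  model <- structure(
    list(assignment = setNames(km$cluster, colnames(m)),
         genes = colnames(m), k = k),
    class = "mult_gene_clusters")
  model$means <- predict(model, m)
  model
}

#' @rdname gene_clustering
#' @param object A `mult_gene_clusters` model.
#' @param newdata Patients x genes table over the training gene set.
#' @param ... Unused.
#' @return For `predict`: patients x `k` matrix of gene-cluster means.
#' @export
predict.mult_gene_clusters <- function(object, newdata, ...) {
  m <- df_to_matrix(newdata)
  if (!identical(colnames(m), object$genes)) {
    abort("gene set does not match the clustering training gene set")
  }
  cl_ids <- sort(unique(object$assignment))
  cols <- map(cl_ids, function(j) {
    members <- names(object$assignment)[object$assignment == j]
    if (length(members) == 0) return(NULL)
    rowMeans(m[, members, drop = FALSE])
  })
  keep <- !vapply(cols, is.null, logical(1))
  if (!all(keep)) warn("dropping empty gene cluster(s)")
  out <- do.call(cbind, cols[keep])
  colnames(out) <- paste0("E_genecluster", cl_ids[keep])
  rownames(out) <- rownames(m)
  out
}
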