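#' Fit a per-marker min-max normalizer
#'
#' Learns `min_M` and `max_M` for every marker on the training table; the
#' transform is `n(m) = (m - min_M) / (max_M - min_M)`.  Constant markers
#' (`max_M == min_M`) map to 0 by convention, which keeps the transform
#' finite; such markers carry no information anyway.
#'
#' @param train Data frame (optionally with `patient_id`) or numeric matrix
#'   of training-set marker values.
#' @return A `mult_normalizer` object.
#' @seealso [apply_normalizer()]
#' @export
fit_normalizer <- function(train) {
  m <- df_to_matrix(train)
  if (nrow(m) == 0 || ncol(m) == 0) abort("empty training matrix")
  structure(
    list(min = apply(m, 2, min, na.rm = TRUE),
         max = apply(m, 2, max, na.rm = TRUE),
         markers = colnames(m)),
    class = "mult_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Training data is transformed with `clip = FALSE`; validation data uses
#' `clip = TRUE`, i.e. `min(1, max(0, n(m)))`, so values outside the
#' training range are limited to `[0, 1]` instead of extrapolating.
#'
#' @param data Data frame (optionally with `patient_id`) or numeric matrix;
#'   its marker names must be a subset of those the normalizer was fit on.
#' @param norm A [fit_normalizer()] object.
#' @param clip Clamp the output into `[0, 1]` (use for validation data).
#' @return Tibble (or matrix, matching the input) of normalized values.
#' @export
apply_normalizer <- function(data, norm, clip = FALSE) {
  was_matrix <- is.matrix(data)
  m <- df_to_matrix(data)
  unknown <- setdiff(colnames(m), norm$markers)
  if (length(unknown) > 0) {
    abort(paste0("marker(s) not seen by the normalizer: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  lo <- norm$min[colnames(m)]
  hi <- norm$max[colnames(m)]
  rng <- hi - lo
  out <- sweep(m, 2, lo, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  if (was_matrix) return(out)
  res <- matrix_to_tbl(out)
  if (is.data.frame(data) && "patient_id" %in% names(data) &&
      !"patient_id" %in% names(res)) {
    res <- bind_cols(tibble(patient_id = as.character(data$patient_id)), res)
  }
  res
}

#' @export
print.mult_normalizer <- function(x, ...) {
  cat("<mult_normalizer> ", length(x$markers), " markers (",
      sum(x$max == x$min), " constant)\n", sep = "")
  invisible(x)
}

#' @rdname fit_normalizer
#' @param x A `mult_normalizer`.
#' @param ... Unused.
#' @export
tidy.mult_normalizer <- function(x, ...) {
  tibble(marker = x$markers, min = unname(x$min), max = unname(x$max))
}
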