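#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Tests whether the marker values of the two outcome classes originate
#' from the same distribution.  Two-sided; exact null distribution is used
#' where [stats::ks.test()] supports it (small samples without ties).
#'
#' @param values_class0,values_class1 Non-empty numeric vectors of marker
#'   values in each outcome class.
#' @return P-value in `[0, 1]`.
#' @export
ks_pvalue <- function(values_class0, values_class1) {
  if (length(values_class0) == 0 || length(values_class1) == 0) {
    abort("both classes must contain at least one value")
  }
  suppressWarnings(
    ks.test(values_class0, values_class1, alternative = "two.sided")$p.value)
}

#' Select outcome-relevant, non-redundant markers
#'
#' The marker-selection algorithm behind both the gene-selection and the
#' clinical-marker-selection steps.  Each marker is scored with a
#' two-sample KS test between the two outcome classes; markers with
#' p-value above `alpha` are excluded as irrelevant.  Surviving markers
#' are compared pairwise: when the absolute Pearson correlation of a pair
#' exceeds `beta`, the member with the larger p-value is excluded as
#' redundant (its information is embedded in the more significant marker).
#'
#' Markers are processed in ascending order of KS p-value (ties broken
#' lexicographically by name), so the kept member of any correlated pair
#' is deterministic and maximally significant.  A marker that has already
#' been excluded is skipped both as an anchor and as a comparison partner,
#' and an anchor excluded inside its own comparison loop stops comparing.
#' P-values are computed once per marker and cached.
#'
#' @param features Data frame (optionally with `patient_id`) or numeric
#'   matrix of normalized marker values, markers in columns.
#' @param outcome Binary (0/1) vector aligned with the feature rows.
#' @param alpha KS significance level; markers with `p > alpha` drop.
#' @param beta Absolute Pearson correlation above which a pair is
#'   considered linearly redundant.
#' @param role Label stored with the report (e.g. `"gene"`, `"clinical"`).
#'
#' @return A `mult_selection` tibble with one row per input marker:
#'   `marker`, `p_value`, `status` (`selected`, `excluded_irrelevant`,
#'   `excluded_redundant`), `redundant_to`, `role`; attributes `alpha`,
#'   `beta`, and `selected` (the surviving marker names, in processing
#'   order).
#' @export
select_markers <- function(features, outcome, alpha = 0.05, beta = 0.75,
                           role = "marker") {
  m <- df_to_matrix(features)
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(m)) {
    abort("outcome length does not match the number of feature rows")
  }
  if (!all(outcome %in% c(0L, 1L))) abort("outcome must be binary 0/1")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (!(beta > 0 && beta <= 1)) abort("beta must lie in (0, 1]")
  if (sum(outcome == 0) == 0 || sum(outcome == 1) == 0) {
    abort("both outcome classes must be present")
  }

  markers <- colnames(m)
  if (is.null(markers) || anyDuplicated(markers)) {
    abort("feature columns must carry unique names")
  }
  i0 <- outcome == 0L
  pvals <- vapply(markers, function(nm) ks_pvalue(m[i0, nm], m[!i0, nm]),
                  numeric(1))

  ord <- markers[order(pvals, markers)]
  excluded <- character(0)
  analysed <- character(0)
  reason <- setNames(rep(NA_character_, length(markers)), markers)
  red_to <- setNames(rep(NA_character_, length(markers)), markers)

  for (m1 in ord) {
    if (m1 %in% excluded) next
    analysed <- c(analysed, m1)
    if (pvals[m1] > alpha) {
      excluded <- c(excluded, m1)
      reason[m1] <- "excluded_irrelevant"
      next
    }
    for (m2 in setdiff(ord, analysed)) {
      if (m2 %in% excluded) next
      if (pvals[m2] > alpha) {
        excluded <- c(excluded, m2)
        reason[m2] <- "excluded_irrelevant"
        next
      }
      pc <- abs(safe_cor(m[, m1], m[, m2]))
      if (pc > beta) {
        if (pvals[m2] >= pvals[m1]) {
          excluded <- c(excluded, m2)
          reason[m2] <- "excluded_redundant"
          red_to[m2] <- m1
        } else {
          excluded <- c(excluded, m1)
          reason[m1] <- "excluded_redundant"
          red_to[m1] <- m2
          break
        }
      }
    }
  }
  selected <- setdiff(ord, excluded)
  reason[selected] <- "selected"

  out <- tibble(
    marker = ord,
    p_value = unname(pvals[ord]),
    status = unname(reason[ord]),
    redundant_to = unname(red_to[ord]),
    role = role)
  class(out) <- c("mult_selection", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "selected") <- selected
  out
}

#' Surviving marker names of a selection report
#' @param report A [select_markers()] report.
#' @return Character vector of selected markers, most significant first.
#' @export
selected_markers <- function(report) attr(report, "selected")

#' @rdname select_markers
#' @param x A `mult_selection` report.
#' @param ... Unused.
#' @export
tidy.mult_selection <- function(x, ...) {
  as_tibble(x)
}

#' @rdname select_markers
#' @export
glance.mult_selection <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_selected = sum(x$status == "selected"),
    n_irrelevant = sum(x$status == "excluded_irrelevant"),
    n_redundant = sum(x$status == "excluded_redundant"),
    alpha = attr(x, "alpha"),
    beta = attr(x, "beta"))
}

#' Write a selection report to TSV
#' @param report A [select_markers()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}
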