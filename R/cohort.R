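#' Treatment-sensitivity cohort
#'
#' A `mult_cohort` bundles the aligned per-patient tables every pipeline
#' stage consumes: an encoded clinical-marker table, a non-negative
#' gene-expression table, the first-line treatment label, the ordered
#' treatment-response class, the derived binary sensitivity outcome (once
#' known) and optional days-to-disease-progression survival columns.  All
#' tables share the same patient order (lexicographic by id).
#'
#' @param patients Data frame with columns `patient_id`, `treatment`,
#'   `response` (one of `r paste(tr_classes(), collapse = ", ")` or `NA`),
#'   and optionally `ts` (0/1), `ddp_days`, `ddp_event`.
#' @param clinical Data frame: `patient_id` plus numeric encoded clinical
#'   markers.  `NA`s are allowed until [filter_cohort()] imputes them.
#' @param expression Data frame: `patient_id` plus non-negative numeric
#'   gene-expression columns (no missing values).
#' @param fish Optional data frame: `patient_id` plus 0/1 FISH marker calls.
#' @param ground_truth Optional list recording planted structure (synthetic
#'   cohorts only); see [generate_cohort()].
#'
#' @return An object of class `mult_cohort`.
#' @seealso [generate_cohort()], [load_cohort()], [filter_cohort()]
#' @export
mult_cohort <- function(patients, clinical, expression, fish = NULL,
                        ground_truth = NULL) {
  patients <- as_tibble(patients)
  clinical <- as_tibble(clinical)
  expression <- as_tibble(expression)
  for (nm in c("patient_id", "treatment")) {
    if (!nm %in% names(patients)) abort(paste0("patients lacks column ", nm))
  }
  if (!"response" %in% names(patients)) patients$response <- NA_character_
  patients$patient_id <- as.character(patients$patient_id)
  ord <- order(patients$patient_id)
  patients <- patients[ord, , drop = FALSE]

  align <- function(tbl, what) {
    if (!"patient_id" %in% names(tbl)) abort(paste0(what, " lacks patient_id"))
    tbl$patient_id <- as.character(tbl$patient_id)
    if (!setequal(tbl$patient_id, patients$patient_id)) {
      abort(paste0(what, " patient ids do not match the patients table"))
    }
    tbl[match(patients$patient_id, tbl$patient_id), , drop = FALSE]
  }
  clinical <- align(clinical, "clinical")
  expression <- align(expression, "expression")
  if (!is.null(fish)) fish <- align(as_tibble(fish), "fish")

  em <- df_to_matrix(expression)
  if (anyNA(em)) abort("expression matrix contains missing values")
  if (any(em < 0)) abort("expression matrix contains negative values")

  bad_resp <- setdiff(unique(patients$response[!is.na(patients$response)]),
                      tr_classes())
  if (length(bad_resp) > 0) {
    abort(paste0("unknown response class(es): ", paste(bad_resp, collapse = ", ")))
  }
  structure(
    list(patients = patients, clinical = clinical, expression = expression,
         fish = fish, ground_truth = ground_truth),
    class = "mult_cohort"
  )
}

#' The six ordered treatment-response classes
#'
#' Depth-of-response order, shallowest first: progressive disease (PD),
#' stable disease (SD), partial response (PR), very good partial response
#' (VGPR), complete response (CR), stringent complete response (SCR).
#'
#' @return Character vector of length six.
#' @export
tr_classes <- function() c("PD", "SD", "PR", "VGPR", "CR", "SCR")

#' @export
print.mult_cohort <- function(x, ...) {
  cat("<mult_cohort> ", nrow(x$patients), " patients, ",
      ncol(x$clinical) - 1L, " clinical markers, ",
      ncol(x$expression) - 1L, " genes\n", sep = "")
  tt <- table(x$patients$treatment)
  cat("treatments: ", paste0(names(tt), " (", tt, ")", collapse = ", "), "\n",
      sep = "")
  if (!all(is.na(x$patients$response))) {
    cat("response classes observed: ",
        paste(intersect(tr_classes(), unique(x$patients$response)),
              collapse = " < "), "\n", sep = "")
  }
  if (!is.null(x$patients$ts) && !all(is.na(x$patients$ts))) {
    cat("sensitive fraction: ",
        round(mean(x$patients$ts, na.rm = TRUE), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A [mult_cohort()].
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.csv$", path)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Load a cohort from delimited files
#'
#' Reads the four (optionally five) per-patient tables and inner-joins them
#' on `patient_id`; the resulting patient order is lexicographic by id.
#' Files may be TSV (default) or CSV (by extension), each with a header row
#' and a `patient_id` column.
#'
#' @param clinical_path Encoded (numeric) clinical marker table.
#' @param expression_path Gene-expression table, genes in columns.
#' @param treatment_path Two columns: `patient_id`, `treatment`.
#' @param response_path Two columns: `patient_id`, `response`.
#' @param survival_path Optional: `patient_id`, `ddp_days`, `ddp_event`.
#' @param fish_path Optional binary FISH marker table.
#'
#' @return A [mult_cohort()].
#' @export
load_cohort <- function(clinical_path, expression_path, treatment_path,
                        response_path, survival_path = NULL,
                        fish_path = NULL) {
  clinical <- read_table_auto(clinical_path)
  expression <- read_table_auto(expression_path)
  treatment <- read_table_auto(treatment_path)
  response <- read_table_auto(response_path)

  for (tbl_nm in c("clinical", "expression", "treatment", "response")) {
    tbl <- get(tbl_nm)
    if (!"patient_id" %in% names(tbl)) {
      abort(paste0("format error: ", tbl_nm, " file lacks a patient_id column"))
    }
  }
  ## expression cells must parse as numbers; name the first offender
  for (cn in setdiff(names(expression), "patient_id")) {
    if (!is.numeric(expression[[cn]])) {
      suppressWarnings(conv <- as.numeric(expression[[cn]]))
      bad <- which(is.na(conv) & !is.na(expression[[cn]]))
      if (length(bad) > 0) {
        abort(paste0("format error: non-numeric expression value '",
                     expression[[cn]][bad[1]], "' in gene ", cn,
                     ", data row ", bad[1]))
      }
      expression[[cn]] <- conv
    }
  }

  ids <- Reduce(intersect, list(as.character(clinical$patient_id),
                                as.character(expression$patient_id),
                                as.character(treatment$patient_id),
                                as.character(response$patient_id)))
  if (length(ids) == 0) abort("empty join: no patient id present in all files")

  patients <- tibble(patient_id = sort(ids)) |>
    inner_join(mutate(treatment, patient_id = as.character(.data$patient_id)),
               by = "patient_id") |>
    inner_join(mutate(response, patient_id = as.character(.data$patient_id)),
               by = "patient_id")
  if (!is.null(survival_path)) {
    surv <- read_table_auto(survival_path)
    patients <- left_join(
      patients, mutate(surv, patient_id = as.character(.data$patient_id)),
      by = "patient_id")
  }
  keep <- function(tbl) {
    tbl$patient_id <- as.character(tbl$patient_id)
    filter(tbl, .data$patient_id %in% ids)
  }
  fish <- if (!is.null(fish_path)) keep(read_table_auto(fish_path)) else NULL
  mult_cohort(patients, keep(clinical), keep(expression), fish = fish)
}

#' Write a cohort to a directory of TSV files
#'
#' Inverse of [load_cohort()]: writes `clinical.tsv`, `expression.tsv`,
#' `treatment.tsv`, `response.tsv`, plus `survival.tsv` / `fish.tsv` /
#' `ground_truth.tsv` when present.
#'
#' @param cohort A [mult_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, nm) {
    readr::write_tsv(tbl, file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  w(cohort$clinical, "clinical")
  w(cohort$expression, "expression")
  w(select(cohort$patients, "patient_id", "treatment"), "treatment")
  w(select(cohort$patients, "patient_id", "response"), "response")
  if (all(c("ddp_days", "ddp_event") %in% names(cohort$patients))) {
    w(select(cohort$patients, "patient_id", "ddp_days", "ddp_event"),
      "survival")
  }
  if (!is.null(cohort$fish)) w(cohort$fish, "fish")
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    w(tibble(patient_id = cohort$patients$patient_id,
             true_ts = gt$ts,
             optimal_treatment = gt$optimal_treatment),
      "ground_truth")
  }
  invisible(dir)
}

#' Subset a cohort by patient index or id
#'
#' @param cohort A [mult_cohort()].
#' @param idx Integer/logical index into the patient order, or character ids.
#' @return A [mult_cohort()] with the selected patients (re-sorted by id).
#' @export
cohort_subset <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$patients$patient_id)
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    li <- if (is.logical(idx)) which(idx) else idx
    ord <- order(cohort$patients$patient_id[li])
    gt <- modifyList(gt, list(
      ts = gt$ts[li][ord],
      optimal_treatment = gt$optimal_treatment[li][ord]
    ))
  }
  mult_cohort(cohort$patients[idx, , drop = FALSE],
              cohort$clinical[idx, , drop = FALSE],
              cohort$expression[idx, , drop = FALSE],
              fish = if (!is.null(cohort$fish)) cohort$fish[idx, , drop = FALSE],
              ground_truth = gt)
}

#' Encode a raw clinical table into a numeric feature table
#'
#' Nominal markers expand into one 0/1 column per level (`marker=level`),
#' ordinal markers map to sequential integers starting at one following the
#' declared level order, numeric markers pass through.  Missing values are
#' replaced by zero when `impute_missing = TRUE`; either way the
#' pre-imputation missingness pattern is attached as the `missing_mask`
#' attribute so marker-level missingness filters can run on it.
#'
#' @param raw Data frame with `patient_id` and raw marker columns.
#' @param schema Named list, one entry per marker column: `list(type =
#'   "nominal"|"ordinal"|"numeric", levels = c(...))` (`levels` required for
#'   ordinal, optional for nominal).  Columns absent from the schema are
#'   treated as numeric.
#' @param impute_missing Replace missing values by zero (default `TRUE`).
#'
#' @return Tibble of `patient_id` plus numeric columns, with a
#'   `missing_mask` attribute (logical matrix over the encoded columns).
#' @export
encode_markers <- function(raw, schema = list(), impute_missing = TRUE) {
  raw <- as_tibble(raw)
  has_id <- "patient_id" %in% names(raw)
  cols <- setdiff(names(raw), "patient_id")
  enc <- list()
  miss <- list()
  for (cn in cols) {
    x <- raw[[cn]]
    sc <- schema[[cn]] %||% list(type = "numeric")
    type <- sc$type %||% "numeric"
    if (type == "nominal") {
      levs <- sc$levels %||% sort(unique(as.character(x[!is.na(x)])))
      m <- one_hot(ifelse(is.na(x), levs[1], as.character(x)), levs, cn)
      m[is.na(x), ] <- 0
      enc[[cn]] <- m
      miss[[cn]] <- matrix(rep(is.na(x), ncol(m)), ncol = ncol(m),
                           dimnames = list(NULL, colnames(m)))
    } else if (type == "ordinal") {
      levs <- sc$levels
      if (is.null(levs)) abort(paste0("schema error: ordinal marker ", cn,
                                      " lacks declared levels"))
      bad <- setdiff(unique(as.character(x[!is.na(x)])), levs)
      if (length(bad) > 0) {
        abort(paste0("schema error: value(s) ", paste(bad, collapse = ", "),
                     " of ordinal marker ", cn, " outside declared levels"))
      }
      v <- as.numeric(match(as.character(x), levs))
      enc[[cn]] <- matrix(v, ncol = 1, dimnames = list(NULL, cn))
      miss[[cn]] <- matrix(is.na(x), ncol = 1, dimnames = list(NULL, cn))
    } else {
      v <- suppressWarnings(as.numeric(x))
      enc[[cn]] <- matrix(v, ncol = 1, dimnames = list(NULL, cn))
      miss[[cn]] <- matrix(is.na(v), ncol = 1, dimnames = list(NULL, cn))
    }
  }
  em <- do.call(cbind, enc)
  mm <- do.call(cbind, miss)
  if (impute_missing) em[is.na(em)] <- 0
  out <- as_tibble(em, .name_repair = "minimal")
  if (has_id) out <- bind_cols(tibble(patient_id = as.character(raw$patient_id)), out)
  attr(out, "missing_mask") <- mm
  out
}

#' Filter a cohort the way the training pipeline expects it
#'
#' Three rules, applied in order: (1) drop patients whose first-line
#' treatment-response class is missing; (2) drop all patients of any
#' treatment with fewer than `min_treatment_n` patients; (3) drop clinical
#' markers whose pre-imputation missing fraction (among the remaining
#' patients) exceeds `max_missing_frac`.  Remaining missing clinical values
#' are then imputed with zero, so the output cohort is complete.
#'
#' @param cohort A [mult_cohort()]; missing clinical values may be `NA`.
#' @param min_treatment_n Minimum patients per retained treatment.
#' @param max_missing_frac Maximum tolerated per-marker missing fraction.
#'
#' @return The filtered [mult_cohort()], with a `filter_log` attribute
#'   (tibble: `entity`, `name`, `reason`, `count`).
#' @export
filter_cohort <- function(cohort, min_treatment_n = 10,
                          max_missing_frac = 0.10) {
  log <- list()
  p <- cohort$patients

  drop_resp <- is.na(p$response)
  if (any(drop_resp)) {
    log[[length(log) + 1]] <- tibble(
      entity = "patient", name = p$patient_id[drop_resp],
      reason = "missing_response", count = 1L)
  }
  keep <- !drop_resp

  tcounts <- table(p$treatment[keep])
  small <- names(tcounts)[tcounts < min_treatment_n]
  if (length(small) > 0) {
    log[[length(log) + 1]] <- tibble(
      entity = "treatment", name = small, reason = "fewer_than_min_patients",
      count = as.integer(tcounts[small]))
    keep <- keep & !(p$treatment %in% small)
  }
  if (!any(keep)) abort("empty cohort: all patients removed by filtering")

  clin <- cohort$clinical[keep, , drop = FALSE]
  cm <- df_to_matrix(clin)
  miss_frac <- colMeans(is.na(cm))
  drop_mk <- names(miss_frac)[miss_frac > max_missing_frac]
  if (length(drop_mk) > 0) {
    log[[length(log) + 1]] <- tibble(
      entity = "marker", name = drop_mk, reason = "missing_fraction_above_max",
      count = as.integer(round(miss_frac[drop_mk] * nrow(cm))))
    clin <- clin[, !(names(clin) %in% drop_mk), drop = FALSE]
  }
  clin <- mutate(clin, dplyr::across(dplyr::where(is.numeric),
                                     ~ ifelse(is.na(.x), 0, .x)))

  out <- mult_cohort(
    cohort$patients[keep, , drop = FALSE], clin,
    cohort$expression[keep, , drop = FALSE],
    fish = if (!is.null(cohort$fish)) cohort$fish[keep, , drop = FALSE],
    ground_truth = subset_ground_truth(cohort, keep))
  attr(out, "filter_log") <- if (length(log) > 0) bind_rows(log) else
    tibble(entity = character(), name = character(), reason = character(),
           count = integer())
  out
}

subset_ground_truth <- function(cohort, keep) {
  gt <- cohort$ground_truth
  if (is.null(gt)) return(NULL)
  li <- if (is.logical(keep)) which(keep) else keep
  ord <- order(cohort$patients$patient_id[li])
  modifyList(gt, list(ts = gt$ts[li][ord],
                      optimal_treatment = gt$optimal_treatment[li][ord]))
}

#' Write a filter log to TSV
#' @param cohort A filtered cohort (output of [filter_cohort()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(cohort, path) {
  log <- attr(cohort, "filter_log")
  if (is.null(log)) abort("cohort carries no filter log")
  readr::write_tsv(log, path, progress = FALSE)
  invisible(path)
}
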