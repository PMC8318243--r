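#' Counterfactual treatment simulation
#'
#' Scores every patient under every candidate treatment by overwriting
#' the one-hot treatment block (all other features untouched) and
#' predicting the TS score, then assigns each patient the
#' score-maximizing treatment kappa.  The switch indicator zeta is 1 iff
#' kappa differs from the actual treatment; the cohort-level switch
#' fraction is the mean of zeta.  Ties are resolved conservatively: if
#' the actual treatment is among the maximizers it is kept (no switch is
#' reported on an exact tie), otherwise the lexicographically first
#' maximizer wins.
#'
#' The cohort is never mutated; scoring runs on a copy of the feature
#' rows.
#'
#' @param model A fitted [train_mult()] model.
#' @param cohort A [mult_cohort()] of patients to simulate (typically a
#'   held-out validation fold).
#' @param candidate_treatments Treatments to simulate; must be a subset
#'   of the model's treatment vocabulary.  Defaults to all of it.
#' @return A `mult_simulation`: tibble with `patient_id`, `actual`, one
#'   `score_<treatment>` column per candidate, `kappa` and `switch`;
#'   attribute `switch_fraction`.
#' @export
simulate_treatments <- function(model, cohort, candidate_treatments = NULL) {
  cands <- candidate_treatments %||% model$treatments
  outside <- setdiff(cands, model$treatments)
  if (length(outside) > 0) {
    abort(paste0("candidate treatment(s) outside the training vocabulary: ",
                 paste(outside, collapse = ", ")))
  }
  score_mat <- vapply(cands, function(tr) {
    predict(model, cohort, treatment = tr)$score
  }, numeric(n_patients(cohort)))
  score_mat <- matrix(score_mat, nrow = n_patients(cohort),
                      dimnames = list(NULL, cands))
  actual <- cohort$patients$treatment
  kappa <- vapply(seq_len(nrow(score_mat)), function(i) {
    maxima <- cands[score_mat[i, ] == max(score_mat[i, ])]
    if (actual[i] %in% maxima) actual[i] else sort(maxima)[1]
  }, character(1))

  tbl <- bind_cols(
    tibble(patient_id = cohort$patients$patient_id, actual = actual),
    as_tibble(score_mat, .name_repair = ~ paste0("score_", .x)),
    tibble(kappa = kappa, switch = as.integer(kappa != actual)))
  new_simulation(tbl, cands)
}

new_simulation <- function(tbl, candidates) {
  structure(tbl, class = c("mult_simulation", class(tbl)),
            candidates = candidates,
            switch_fraction = mean(tbl$switch))
}

pool_simulations <- function(sims) {
  cands <- attr(sims[[1]], "candidates")
  new_simulation(bind_rows(map(sims, as_tibble)), cands)
}

#' Switch fraction of a simulation
#' @param sim A [simulate_treatments()] table.
#' @return Fraction of patients whose score-maximizing treatment differs
#'   from the actual one.
#' @export
switch_fraction <- function(sim) attr(sim, "switch_fraction")

#' Treatment-reallocation matrix
#'
#' Entry (a, b) is the percentage of patients that received treatment `a`
#' while the simulation indicated treatment `b`; each row sums to 100.
#' Treatments with zero patients are omitted.
#'
#' @param table A [simulate_treatments()] result.
#' @return Numeric matrix of percentages (actual treatments in rows,
#'   simulated in columns).
#' @export
reallocation_matrix <- function(table) {
  if (nrow(table) == 0) abort("empty simulation table")
  cands <- attr(table, "candidates")
  actual_lv <- intersect(sort(unique(c(table$actual, cands))),
                         unique(table$actual))
  out <- matrix(0, length(actual_lv), length(cands),
                dimnames = list(actual = actual_lv, simulated = cands))
  for (a in actual_lv) {
    rows <- table$actual == a
    tab <- table(factor(table$kappa[rows], levels = cands))
    out[a, ] <- 100 * as.numeric(tab) / sum(rows)
  }
  out
}

#' @export
print.mult_simulation <- function(x, ...) {
  cat("<mult_simulation> ", nrow(x), " patients, switch fraction ",
      round(100 * attr(x, "switch_fraction"), 2), "%\n", sep = "")
  NextMethod()
}

#' @rdname simulate_treatments
#' @param x A `mult_simulation`.
#' @param ... Unused.
#' @export
tidy.mult_simulation <- function(x, ...) as_tibble(x)

#' @rdname simulate_treatments
#' @export
glance.mult_simulation <- function(x, ...) {
  tibble(n_patients = nrow(x),
         n_candidates = length(attr(x, "candidates")),
         switch_fraction = attr(x, "switch_fraction"))
}

#' @rdname simulate_treatments
#' @param object A `mult_simulation`.
#' @export
autoplot.mult_simulation <- function(object, ...) {
  rm_ <- reallocation_matrix(object)
  df <- as_tibble(rm_, rownames = "actual") |>
    pivot_longer(-"actual", names_to = "simulated", values_to = "pct")
  ggplot(df, aes(x = .data$pct, y = .data$actual, fill = .data$simulated)) +
    geom_col(position = "stack") +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "% of patients", y = "actual treatment",
         fill = "simulated\ntreatment",
         title = "Score-maximizing treatment reallocation") +
    theme_minimal()
}
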