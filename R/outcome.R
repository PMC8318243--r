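#' Treatment-sensitivity definition from ordered response classes
#'
#' A cutpoint over the six ordered treatment-response classes
#' (`PD < SD < PR < VGPR < CR < SCR`): every class at or above the cut is
#' the sensitive class.  The clinically established instance groups SCR
#' with CR, i.e. `ts_definition("CR")`.
#'
#' @param sensitive_from The lowest response class counted as sensitive.
#' @param p_table Optional per-candidate stratification p-value table
#'   (filled by [select_ts_definition()]).
#' @return A `ts_definition` object.
#' @export
ts_definition <- function(sensitive_from = "CR", p_table = NULL) {
  classes <- tr_classes()
  if (!sensitive_from %in% classes[-1]) {
    abort(paste0("sensitive_from must be one of: ",
                 paste(classes[-1], collapse = ", ")))
  }
  structure(
    list(classes = classes, sensitive_from = sensitive_from,
         cut_index = match(sensitive_from, classes), p_table = p_table),
    class = "ts_definition")
}

#' @export
print.ts_definition <- function(x, ...) {
  cat("<ts_definition> sensitive = {",
      paste(x$classes[seq_along(x$classes) >= x$cut_index], collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' @rdname ts_definition
#' @param x A `ts_definition`.
#' @param ... Unused.
#' @export
tidy.ts_definition <- function(x, ...) {
  x$p_table %||%
    tibble(sensitive_from = character(), p_value = numeric())
}

#' Derive the binary sensitivity outcome from response classes
#'
#' @param response Character vector of treatment-response classes.
#' @param definition A [ts_definition()].
#' @return Integer 0/1 vector (`NA` where the response is missing): 1 iff
#'   the class is at or above the definition's cut.
#' @export
derive_ts <- function(response, definition = ts_definition("CR")) {
  idx <- match(response, definition$classes)
  bad <- unique(response[is.na(idx) & !is.na(response)])
  if (length(bad) > 0) {
    abort(paste0("unknown response class(es): ", paste(bad, collapse = ", ")))
  }
  as.integer(idx >= definition$cut_index)
}

#' Survival-stratification p-value of a binary outcome
#'
#' P-value of the binary covariate from a Cox proportional-hazards fit
#' (score test, Breslow tie handling), which for a single binary
#' covariate coincides asymptotically with the log-rank test.
#'
#' @param ts Binary 0/1 group indicator.
#' @param time Non-negative survival times (days to disease progression).
#' @param event 1 = progression observed, 0 = censored.
#' @return The score-test p-value; groups with no events in one arm
#'   return 1 with a warning.
#' @export
stratification_pvalue <- function(ts, time, event) {
  keep <- !is.na(ts) & !is.na(time) & !is.na(event)
  ts <- ts[keep]; time <- time[keep]; event <- event[keep]
  if (length(unique(ts)) < 2) abort("both groups must be present")
  ev <- tapply(event, ts, sum)
  if (any(ev == 0)) {
    warn("a group has no events; stratification p-value set to 1")
    return(1)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ ts,
                         ties = "breslow")
  unname(summary(fit)$sctest["pvalue"])
}

#' Choose the sensitivity cut that best stratifies survival
#'
#' Evaluates the five candidate cuts over the six ordered response
#' classes (sensitive = classes at or above SD, PR, VGPR, CR, SCR
#' respectively), fits a Cox proportional-hazards model for each and
#' returns the definition with the minimum stratification p-value, along
#' with the full candidate table.
#'
#' @param response Treatment-response class per patient.
#' @param time,event Survival columns (see [stratification_pvalue()]).
#' @return A [ts_definition()] whose `p_table` lists all five candidates.
#' @export
select_ts_definition <- function(response, time, event) {
  classes <- tr_classes()
  candidates <- classes[-1]
  rows <- map(candidates, function(cut) {
    ts <- derive_ts(response, ts_definition(cut))
    p <- tryCatch(
      withCallingHandlers(
        stratification_pvalue(ts, time, event),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NA_real_)
    tibble(sensitive_from = cut,
           n_sensitive = sum(ts == 1, na.rm = TRUE),
           n_non_sensitive = sum(ts == 0, na.rm = TRUE),
           p_value = p)
  })
  p_table <- bind_rows(rows)
  if (all(is.na(p_table$p_value))) {
    abort("no valid sensitivity cut: degenerate survival data")
  }
  best <- p_table$sensitive_from[which.min(p_table$p_value)]
  ts_definition(best, p_table = p_table)
}
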