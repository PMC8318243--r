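#' Run the complete experiment end to end
#'
#' Load (or accept) a cohort, filter it, fix the sensitivity definition
#' (survival-guided when survival columns are present, the standard
#' CR/SCR cut otherwise), run the equalized cross-validation experiment
#' with the chosen pipeline, optionally run the counterfactual treatment
#' simulation, and write every result table plus a reproducibility
#' manifest to `out_dir`.
#'
#' Outputs: `metrics_per_fold.tsv`, `metrics_pooled.tsv`,
#' `metrics_per_treatment.tsv`, `scores.tsv`, `selection_fold<k>.tsv`,
#' `filter_log.tsv`, `ts_definition.tsv`, `simulation.tsv` and
#' `reallocation.tsv` (pipeline `"mult"`), and `manifest.json` (config
#' hash, seeds, package version, per-stage timings, failure point on
#' error).
#'
#' @param cohort A [mult_cohort()], or `NULL` to load one from `paths`.
#' @param paths Named list of file paths for [load_cohort()] (`clinical`,
#'   `expression`, `treatment`, `response`, optionally `survival`).
#' @param out_dir Output directory.
#' @param pipeline Pipeline to evaluate (see [run_cv()]).
#' @param n_folds Cross-validation folds.
#' @param min_treatment_n,max_missing_frac Cohort filters
#'   (see [filter_cohort()]).
#' @param ts_def Optional fixed [ts_definition()]; when `NULL` it is
#'   selected from survival data if available.
#' @param simulate Run the treatment simulation (pipeline `"mult"`).
#' @param seed Master seed; all stage seeds derive from it.
#' @param control A [mult_control()].
#' @return Invisibly, a list with `cohort`, `ts_def`, `plan`, `cv`,
#'   `simulation` and `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, paths = NULL, out_dir,
                         pipeline = "mult", n_folds = 10,
                         min_treatment_n = 10, max_missing_frac = 0.10,
                         ts_def = NULL, simulate = TRUE, seed = 7,
                         control = mult_control()) {
  if (is.null(cohort) && is.null(paths)) {
    abort("config error: provide either a cohort or input paths")
  }
  if (!is.null(paths)) {
    need <- c("clinical", "expression", "treatment", "response")
    missing_keys <- setdiff(need, names(paths))
    if (length(missing_keys) > 0) {
      abort(paste0("config error: missing input path(s): ",
                   paste(missing_keys, collapse = ", ")))
    }
    bad <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(bad) > 0) {
      abort(paste0("data error: input file(s) not found: ",
                   paste(bad, collapse = ", ")))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(pipeline = pipeline, n_folds = n_folds,
                 min_treatment_n = min_treatment_n,
                 max_missing_frac = max_missing_frac, seed = seed,
                 control = unclass(control))
  manifest <- list(
    package_version = as.character(utils::packageVersion("multsens")),
    config = config, config_hash = rlang::hash(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(), status = "running")
  stage_env <- new.env()
  stage_env$current <- "init"
  run_stage <- function(name, code) {
    stage_env$current <- name
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    manifest$stages[[name]] <<- list(seconds =
      round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  finish <- function(status) {
    manifest$status <- status
    if (status != "ok") manifest$failed_stage <- stage_env$current
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  result <- tryCatch({
    cohort <- run_stage("load", {
      if (!is.null(paths)) {
        load_cohort(paths$clinical, paths$expression, paths$treatment,
                    paths$response, survival_path = paths$survival)
      } else cohort
    })
    cohort <- run_stage("filter", {
      co <- filter_cohort(cohort, min_treatment_n = min_treatment_n,
                          max_missing_frac = max_missing_frac)
      write_filter_log(co, file.path(out_dir, "filter_log.tsv"))
      co
    })
    ts_def <- run_stage("ts_define", {
      td <- ts_def
      if (is.null(td)) {
        has_surv <- all(c("ddp_days", "ddp_event") %in%
                          names(cohort$patients)) &&
          !all(is.na(cohort$patients$ddp_days))
        td <- if (has_surv) {
          select_ts_definition(cohort$patients$response,
                               cohort$patients$ddp_days,
                               cohort$patients$ddp_event)
        } else ts_definition("CR")
      }
      readr::write_tsv(tidy(td) %||% tibble(),
                       file.path(out_dir, "ts_definition.tsv"),
                       progress = FALSE)
      td
    })
    ts <- derive_ts(cohort$patients$response, ts_def)
    plan <- run_stage("cv_plan", {
      make_cv_plan(cohort, n_folds = n_folds, ts = ts,
                   seed = derive_seed(seed, "plan"))
    })
    cv <- run_stage("cross_validation", {
      run_cv(cohort, plan, pipeline = pipeline,
             seed = derive_seed(seed, "cv"), control = control,
             simulate = simulate && pipeline == "mult")
    })
    run_stage("write_results", {
      readr::write_tsv(cv$metrics$per_fold,
                       file.path(out_dir, "metrics_per_fold.tsv"),
                       progress = FALSE)
      readr::write_tsv(cv$metrics$pooled,
                       file.path(out_dir, "metrics_pooled.tsv"),
                       progress = FALSE)
      readr::write_tsv(cv$metrics$per_treatment,
                       file.path(out_dir, "metrics_per_treatment.tsv"),
                       progress = FALSE)
      readr::write_tsv(cv$scores, file.path(out_dir, "scores.tsv"),
                       progress = FALSE)
      walk(names(cv$selections), function(nm) {
        rep <- cv$selections[[nm]]
        if (inherits(rep, "mult_selection")) rep <- list(rep)
        readr::write_tsv(bind_rows(map(rep, as_tibble)),
                         file.path(out_dir, paste0("selection_", nm, ".tsv")),
                         progress = FALSE)
      })
      if (!is.null(cv$simulation)) {
        readr::write_tsv(as_tibble(cv$simulation),
                         file.path(out_dir, "simulation.tsv"),
                         progress = FALSE)
        rm_ <- reallocation_matrix(cv$simulation)
        readr::write_tsv(as_tibble(rm_, rownames = "actual"),
                         file.path(out_dir, "reallocation.tsv"),
                         progress = FALSE)
      }
    })
    list(cohort = cohort, ts_def = ts_def, plan = plan, cv = cv,
         simulation = cv$simulation)
  }, error = function(e) {
    finish("failed")
    abort(paste0("pipeline error at stage '", stage_env$current, "': ",
                 conditionMessage(e)), parent = e)
  })
  finish("ok")
  result$manifest <- manifest
  invisible(result)
}
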