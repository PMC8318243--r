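#' Configuration for the synthetic cohort generator
#'
#' The generator plants the structure the pipeline is designed to exploit:
#' a minority "sensitive" class defined through the six ordered
#' treatment-response categories, a small set of truly informative genes
#' among many null genes, near-duplicate (redundant) copies of informative
#' genes, informative clinical markers, missing clinical values, uneven
#' treatment prevalence, survival times whose hazard separates by
#' sensitivity class, and optionally a treatment-by-biomarker interaction
#' that gives a latent subgroup a preferred treatment.
#'
#' Defaults mirror a mid-sized newly-diagnosed multiple-myeloma cohort:
#' five first-line treatments with uneven prevalence (including
#' "Non-treatment"), roughly 30% of patients in the sensitive class, gene
#' abundances drawn log-normally, a 1-standard-deviation (log-scale) shift
#' of informative markers between sensitivity classes, 5% missing clinical
#' values, a hazard ratio of 3 between sensitivity classes and 20%
#' censoring.
#'
#' @param n_patients Number of patients.
#' @param n_genes Total genes (informative + redundant copies + null).
#' @param n_informative_genes Genes shifted between sensitivity classes.
#' @param n_redundant_copies Near-duplicate copies per informative gene.
#' @param redundant_noise_sd Log-scale noise sd of each redundant copy.
#' @param n_clinical_markers Total numeric clinical markers.
#' @param n_informative_clinical Clinical markers shifted between classes.
#' @param treatments Named numeric vector: treatment prevalence weights.
#' @param sensitive_fraction Marginal probability of the sensitive class.
#' @param effect_size Mean shift (in noise-sd units, log scale for genes)
#'   of informative markers between sensitivity classes.
#' @param interaction Optional list
#'   `list(treatment =, n_markers =, shift =, marker_shift =)`: a random
#'   half of patients is latently "responsive"; their first `n_markers`
#'   informative genes are shifted by `marker_shift` and their log-odds of
#'   sensitivity increase by `shift` when treated with `treatment`.
#' @param missing_frac Per-cell probability of a missing clinical value.
#' @param hazard_ratio Hazard ratio (non-sensitive vs sensitive) of the
#'   exponential days-to-disease-progression times.
#' @param censoring_frac Target fraction of censored survival times.
#' @param baseline_median_ddp Median days to progression, non-sensitive.
#' @param seed Integer; fully determines the generated cohort.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 600,
                         n_genes = 500,
                         n_informative_genes = 10,
                         n_redundant_copies = 1,
                         redundant_noise_sd = 0.01,
                         n_clinical_markers = 20,
                         n_informative_clinical = 5,
                         treatments = c("Bor-Cyc-Dex" = 133, "Bor-Dex" = 64,
                                        "Bor-Len-Dex" = 236, "Len-Dex" = 50,
                                        "Non-treatment" = 232),
                         sensitive_fraction = 0.30,
                         effect_size = 1,
                         interaction = NULL,
                         missing_frac = 0.05,
                         hazard_ratio = 3,
                         censoring_frac = 0.20,
                         baseline_median_ddp = 700,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 2, n_genes >= 1, n_clinical_markers >= 1)
  for (f in c("sensitive_fraction", "missing_frac", "censoring_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("config error: ", f, " must lie in [0, 1]"))
    }
  }
  if (sensitive_fraction <= 0 || sensitive_fraction >= 1) {
    abort("config error: sensitive_fraction must be strictly inside (0, 1)")
  }
  need <- n_informative_genes * (1 + n_redundant_copies)
  if (need > n_genes) {
    abort(paste0("config error: informative genes plus redundant copies (",
                 need, ") exceed n_genes (", n_genes, ")"))
  }
  if (n_informative_clinical > n_clinical_markers) {
    abort("config error: n_informative_clinical exceeds n_clinical_markers")
  }
  if (is.null(names(treatments)) || any(treatments < 0) ||
      sum(treatments) == 0) {
    abort("config error: treatments must be a named non-negative weight vector")
  }
  if (!is.null(interaction)) {
    if (!interaction$treatment %in% names(treatments)) {
      abort("config error: interaction treatment not in treatment set")
    }
    if (interaction$n_markers > n_informative_genes) {
      abort("config error: interaction n_markers exceeds informative genes")
    }
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a complete [mult_cohort()] from a [synth_config()].  The returned
#' cohort's `ground_truth` field records which markers are informative,
#' which genes are redundant duplicates of which, each patient's true
#' sensitivity class and (where an interaction is planted) latent optimal
#' treatment -- enough to score selection recall and simulation recovery
#' without re-deriving labels.
#'
#' Treatment-response classes are assigned by thresholding a latent
#' response propensity into six ordered bins such that the sensitive class
#' is exactly \{CR, SCR\}; survival times are exponential with the hazard
#' separation of the config.
#'
#' @param config A [synth_config()].
#' @return A [mult_cohort()] whose `ground_truth` is a list with elements
#'   `informative_genes`, `redundant_map`, `informative_clinical`, `ts`,
#'   `responsive`, `optimal_treatment` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_patients
  with_seed(cfg$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    treatment <- sample(names(cfg$treatments), n, replace = TRUE,
                        prob = cfg$treatments / sum(cfg$treatments))

    responsive <- rep(FALSE, n)
    base_logit <- qlogis(cfg$sensitive_fraction)
    eta <- rep(base_logit, n)
    if (!is.null(cfg$interaction)) {
      responsive <- runif(n) < 0.5
      eta <- eta + cfg$interaction$shift *
        (responsive & treatment == cfg$interaction$treatment)
    }
    ts <- as.integer(runif(n) < plogis(eta))

    ## six ordered response bins via a latent propensity; the top two bins
    ## (CR, SCR) are exactly the sensitive class
    u <- runif(n)
    response <- ifelse(
      ts == 1,
      c("CR", "SCR")[1 + (u > 0.5)],
      tr_classes()[1 + findInterval(u, c(0.25, 0.50, 0.75))])

    ## genes: log-normal abundances; informative genes shifted by
    ## effect_size (log-scale sd units) between sensitivity classes
    n_inf <- cfg$n_informative_genes
    n_cop <- n_inf * cfg$n_redundant_copies
    gene_names <- sprintf("g%04d", seq_len(cfg$n_genes))
    mu <- rnorm(cfg$n_genes, mean = 2, sd = 0.5)
    logx <- matrix(rnorm(n * cfg$n_genes), n, cfg$n_genes)
    logx <- sweep(logx, 2, mu, "+")
    if (n_inf > 0) {
      logx[, seq_len(n_inf)] <- logx[, seq_len(n_inf)] +
        cfg$effect_size * ts
    }
    if (!is.null(cfg$interaction) && cfg$interaction$n_markers > 0) {
      im <- seq_len(cfg$interaction$n_markers)
      logx[, im] <- logx[, im] + cfg$interaction$marker_shift * responsive
    }
    redundant_map <- tibble(copy = character(), source = character())
    if (n_cop > 0) {
      src <- rep(seq_len(n_inf), each = cfg$n_redundant_copies)
      cop <- n_inf + seq_len(n_cop)
      logx[, cop] <- logx[, src] +
        matrix(rnorm(n * n_cop, sd = cfg$redundant_noise_sd), n, n_cop)
      redundant_map <- tibble(copy = gene_names[cop],
                              source = gene_names[src])
    }
    expression <- exp(logx)
    colnames(expression) <- gene_names

    ## clinical markers: standard-normal, informative ones shifted by ts
    cl_names <- sprintf("cm%02d", seq_len(cfg$n_clinical_markers))
    clin <- matrix(rnorm(n * cfg$n_clinical_markers), n,
                   dimnames = list(NULL, cl_names))
    if (cfg$n_informative_clinical > 0) {
      ic <- seq_len(cfg$n_informative_clinical)
      clin[, ic] <- clin[, ic] + cfg$effect_size * ts
    }
    if (cfg$missing_frac > 0) {
      clin[matrix(runif(length(clin)) < cfg$missing_frac,
                  nrow = n)] <- NA_real_
    }

    ## exponential survival separated by sensitivity class
    rate_ns <- log(2) / cfg$baseline_median_ddp
    rate <- ifelse(ts == 1, rate_ns / cfg$hazard_ratio, rate_ns)
    t_event <- rexp(n, rate)
    if (cfg$censoring_frac > 0) {
      rate_c <- cfg$censoring_frac / (1 - cfg$censoring_frac) * mean(rate)
      t_cens <- rexp(n, rate_c)
    } else {
      t_cens <- rep(Inf, n)
    }
    ddp_days <- ceiling(pmin(t_event, t_cens))
    ddp_event <- as.integer(t_event <= t_cens)

    patients <- tibble(
      patient_id = ids, treatment = treatment, response = response,
      ts = NA_integer_, ddp_days = as.numeric(ddp_days),
      ddp_event = ddp_event)

    opt <- rep(NA_character_, n)
    if (!is.null(cfg$interaction)) opt[responsive] <- cfg$interaction$treatment

    gt <- list(
      informative_genes = gene_names[seq_len(n_inf)],
      redundant_map = redundant_map,
      informative_clinical = cl_names[seq_len(cfg$n_informative_clinical)],
      ts = ts,
      responsive = responsive,
      optimal_treatment = opt,
      config = cfg)

    mult_cohort(
      patients,
      bind_cols(tibble(patient_id = ids),
                as_tibble(clin, .name_repair = "minimal")),
      bind_cols(tibble(patient_id = ids),
                as_tibble(expression, .name_repair = "minimal")),
      ground_truth = gt)
  })
}

#' Generate a binary FISH-marker panel driven by gene expression
#'
#' Each FISH marker is 1 iff a weighted linear score over its driver genes
#' (log scale, standardized) plus Gaussian noise exceeds the
#' `1 - prevalence` quantile of the scores, so the configured prevalence is
#' hit by construction.  With `noise_sd = 0` the label is a deterministic
#' function of the driver genes.  `n_null_markers` additional markers are
#' driven by pure noise (no drivers) and serve as negative controls.
#'
#' @param cohort A [mult_cohort()].
#' @param n_markers Number of driver-based FISH markers.
#' @param driver_gene_sets Optional list of character vectors (one per
#'   marker) naming driver genes; sampled from the cohort's genes when
#'   `NULL`.  An empty driver set is a configuration error.
#' @param genes_per_marker Drivers sampled per marker when
#'   `driver_gene_sets` is `NULL`.
#' @param prevalence Target positive fraction per marker.
#' @param noise_sd Sd of the additive score noise.
#' @param n_null_markers Markers with no drivers (noise only).
#' @param seed Integer seed.
#'
#' @return List: `fish` (tibble of `patient_id` + 0/1 columns), `drivers`
#'   (named list of driver genes per marker; `character(0)` entries are the
#'   null markers), `weights`.
#' @export
generate_fish_panel <- function(cohort, n_markers = 5,
                                driver_gene_sets = NULL,
                                genes_per_marker = 10, prevalence = 0.30,
                                noise_sd = 0.5, n_null_markers = 0,
                                seed = 1) {
  genes <- setdiff(names(cohort$expression), "patient_id")
  if (!is.null(driver_gene_sets)) {
    if (any(lengths(driver_gene_sets) == 0)) {
      abort("config error: empty driver gene set")
    }
    bad <- setdiff(unlist(driver_gene_sets), genes)
    if (length(bad) > 0) {
      abort(paste0("config error: driver gene(s) not in cohort: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    n_markers <- length(driver_gene_sets)
  }
  n <- n_patients(cohort)
  logx <- log(df_to_matrix(cohort$expression) + 1)
  with_seed(seed, {
    drivers <- driver_gene_sets %||%
      replicate(n_markers, sample(genes, genes_per_marker), simplify = FALSE)
    names(drivers) <- paste0("fish", sprintf("%02d", seq_along(drivers)))
    weights <- map(drivers, ~ setNames(runif(length(.x), 0.5, 1.5), .x))
    calls <- imap(drivers, function(dg, nm) {
      z <- scale(logx[, dg, drop = FALSE])
      score <- drop(z %*% weights[[nm]]) + rnorm(n, sd = noise_sd)
      as.integer(score > quantile(score, 1 - prevalence))
    })
    if (n_null_markers > 0) {
      for (j in seq_len(n_null_markers)) {
        nm <- paste0("fish_null", sprintf("%02d", j))
        score <- rnorm(n)
        calls[[nm]] <- as.integer(score > quantile(score, 1 - prevalence))
        drivers[[nm]] <- character(0)
      }
    }
    list(
      fish = bind_cols(tibble(patient_id = cohort$patients$patient_id),
                       as_tibble(calls)),
      drivers = drivers,
      weights = weights)
  })
}
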