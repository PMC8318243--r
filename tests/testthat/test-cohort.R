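write_toy_files <- function(dir, ids_clin, ids_expr, ids_trt, ids_resp) {
  mk <- function(ids, tbl, nm) {
    readr::write_tsv(tbl, file.path(dir, paste0(nm, ".tsv")))
    file.path(dir, paste0(nm, ".tsv"))
  }
  list(
    clinical = mk(ids_clin, tibble::tibble(patient_id = ids_clin,
                                           age = seq_along(ids_clin)),
                  "clinical"),
    expression = mk(ids_expr, tibble::tibble(patient_id = ids_expr,
                                             g1 = seq_along(ids_expr),
                                             g2 = rev(seq_along(ids_expr))),
                    "expression"),
    treatment = mk(ids_trt, tibble::tibble(patient_id = ids_trt,
                                           treatment = "A"), "treatment"),
    response = mk(ids_resp, tibble::tibble(patient_id = ids_resp,
                                           response = "CR"), "response"))
}

test_that("load_cohort inner-joins on patient id", {
  dir <- withr::local_tempdir()
  p <- write_toy_files(dir,
                       ids_clin = c("P1", "P2", "P3", "P4", "P9"),
                       ids_expr = c("P9", "A1", "A2", "A3", "A4"),
                       ids_trt  = c("P9", "B1", "B2", "B3", "B4"),
                       ids_resp = c("P9", "C1", "C2", "C3", "C4"))
  co <- load_cohort(p$clinical, p$expression, p$treatment, p$response)
  expect_equal(n_patients(co), 1L)
  expect_equal(co$patients$patient_id, "P9")
})

test_that("load_cohort reports format problems precisely", {
  dir <- withr::local_tempdir()
  p <- write_toy_files(dir, "P1", "P1", "P1", "P1")
  # corrupt one expression cell
  readr::write_tsv(tibble::tibble(patient_id = c("P1", "P2"),
                                  g1 = c("1.5", "oops")),
                   file.path(dir, "expression.tsv"))
  expect_error(
    load_cohort(p$clinical, file.path(dir, "expression.tsv"),
                p$treatment, p$response),
    "non-numeric.*oops.*g1")
  # missing id column
  readr::write_tsv(tibble::tibble(id = "P1", g1 = 1),
                   file.path(dir, "expression.tsv"))
  expect_error(
    load_cohort(p$clinical, file.path(dir, "expression.tsv"),
                p$treatment, p$response),
    "patient_id")
  # zero overlap
  p2 <- write_toy_files(dir, "P1", "Q1", "P1", "P1")
  expect_error(
    load_cohort(p2$clinical, p2$expression, p2$treatment, p2$response),
    "empty join")
})

test_that("a generated cohort round-trips through write_cohort/load_cohort", {
  co <- generate_cohort(synth_config(n_patients = 30, n_genes = 12,
                                     n_informative_genes = 3,
                                     missing_frac = 0, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- load_cohort(file.path(dir, "clinical.tsv"),
                     file.path(dir, "expression.tsv"),
                     file.path(dir, "treatment.tsv"),
                     file.path(dir, "response.tsv"),
                     survival_path = file.path(dir, "survival.tsv"))
  expect_equal(co2$patients$patient_id, co$patients$patient_id)
  expect_equal(co2$patients$treatment, co$patients$treatment)
  expect_equal(co2$patients$response, co$patients$response)
  expect_equal(co2$patients$ddp_days, co$patients$ddp_days)
  expect_equal(as.data.frame(co2$expression), as.data.frame(co$expression),
               tolerance = 1e-12)
  expect_equal(as.data.frame(co2$clinical), as.data.frame(co$clinical),
               tolerance = 1e-12)
})

test_that("encode_markers implements one-hot, ordinal and zero-imputation", {
  raw <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    race = c("A", "B", NA),
    stage = c("I", "II", "III"),
    age = c(60, NA, 70))
  schema <- list(race = list(type = "nominal", levels = c("A", "B")),
                 stage = list(type = "ordinal",
                              levels = c("I", "II", "III")))
  enc <- encode_markers(raw, schema)
  expect_equal(enc$`race=A`, c(1, 0, 0))
  expect_equal(enc$`race=B`, c(0, 1, 0))
  expect_equal(enc$stage, c(1, 2, 3))
  expect_equal(enc$age, c(60, 0, 70))
  mask <- attr(enc, "missing_mask")
  expect_true(mask[3, "race=A"] && mask[3, "race=B"])
  expect_true(mask[2, "age"])
  expect_false(any(mask[, "stage"]))

  expect_error(
    encode_markers(tibble::tibble(stage = "IV"),
                   list(stage = list(type = "ordinal",
                                     levels = c("I", "II", "III")))),
    "schema error")
})

test_that("filter_cohort applies the response, treatment-size and missingness rules", {
  n <- 40
  ids <- sprintf("P%02d", 1:n)
  patients <- tibble::tibble(
    patient_id = ids,
    treatment = c(rep("big", 30), rep("small", 9), "big"),
    response = c(rep("CR", 38), NA, "PD"))
  clin <- tibble::tibble(patient_id = ids,
                         ok = rnorm(n),
                         leaky = replace(rnorm(n), 1:5, NA))  # 5/40 = 12.5%
  expr <- tibble::tibble(patient_id = ids, g1 = abs(rnorm(n)))
  co <- mult_cohort(patients, clin, expr)
  fc <- filter_cohort(co, min_treatment_n = 10, max_missing_frac = 0.10)

  expect_false(any(fc$patients$treatment == "small"))
  expect_false(any(is.na(fc$patients$response)))
  expect_false("leaky" %in% names(fc$clinical))
  expect_false(anyNA(fc$clinical$ok))
  log <- attr(fc, "filter_log")
  expect_setequal(unique(log$reason),
                  c("missing_response", "fewer_than_min_patients",
                    "missing_fraction_above_max"))

  # idempotence: a clean cohort passes through unchanged
  fc2 <- filter_cohort(fc)
  expect_equal(fc2$patients, fc$patients)
  expect_equal(names(fc2$clinical), names(fc$clinical))
  expect_equal(nrow(attr(fc2, "filter_log")), 0L)

  expect_error(
    filter_cohort(mult_cohort(
      dplyr::mutate(patients, response = NA_character_), clin, expr)),
    "empty cohort")
})

test_that("min-max normalization matches its formula and clips validation data", {
  tr <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2,
               dimnames = list(NULL, c("a", "const")))
  norm <- fit_normalizer(tr)
  out <- apply_normalizer(tr, norm)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "const"], c(0, 0, 0))

  val <- matrix(c(8, 1, 5, 5), ncol = 2, dimnames = list(NULL, c("a", "const")))
  clipped <- apply_normalizer(val, norm, clip = TRUE)
  expect_equal(clipped[, "a"], c(1, 0))

  # brute-force formula oracle on random matrices
  for (s in 1:25) {
    withr::with_seed(s, {
      m <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, letters[1:4]))
      got <- apply_normalizer(m, fit_normalizer(m))
      want <- apply(m, 2, function(x) (x - min(x)) / (max(x) - min(x)))
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
      expect_equal(unname(apply(got, 2, min)), rep(0, 4))
      expect_equal(unname(apply(got, 2, max)), rep(1, 4))
    })
  }
  expect_error(apply_normalizer(matrix(1, 1, 1, dimnames = list(NULL, "zz")),
                                norm),
               "not seen")
})
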