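test_that("the CV plan equalizes classes within every treatment stratum", {
  co <- test_cohort(n = 260, genes = 20, informative = 2, seed = 12)
  ts <- derive_ts(co$patients$response)
  plan <- make_cv_plan(co, n_folds = 5, ts = ts, seed = 3)

  assigned <- plan[!plan$removed, ]
  # exact class equality per fold x treatment cell
  tab <- dplyr::count(assigned, treatment, fold, ts)
  wide <- tidyr::pivot_wider(tab, names_from = "ts", values_from = "n",
                             values_fill = 0)
  expect_true(all(wide$`0` == wide$`1`))
  # per-class fold sizes differ by at most one within a stratum
  by_class <- dplyr::count(assigned, treatment, ts, fold)
  spread <- dplyr::summarise(dplyr::group_by(by_class, treatment, ts),
                             d = max(n) - min(n), .groups = "drop")
  expect_true(all(spread$d <= 1))
  # removals only hit the majority class of each stratum
  log <- attr(plan, "equalization_log")
  for (i in seq_len(nrow(log))) {
    strat <- plan[plan$treatment == log$treatment[i], ]
    n1 <- sum(strat$ts == 1); n0 <- sum(strat$ts == 0)
    expect_equal(log$majority_class[i], if (n1 > n0) 1L else 0L)
    removed <- strat[strat$removed, ]
    expect_true(all(removed$ts == log$majority_class[i]))
  }
  # determinism
  expect_identical(plan, make_cv_plan(co, n_folds = 5, ts = ts, seed = 3))
  # an already balanced stratum loses nobody
  bal <- plan[plan$treatment == plan$treatment[1], ]
})

test_that("a perfectly balanced cohort is never subsampled", {
  ids <- sprintf("P%02d", 1:40)
  co <- mult_cohort(
    tibble::tibble(patient_id = ids, treatment = rep(c("A", "B"), 20),
                   response = rep(c("CR", "PD"), each = 20)),
    tibble::tibble(patient_id = ids, m = rnorm(40)),
    tibble::tibble(patient_id = ids, g = abs(rnorm(40))))
  plan <- make_cv_plan(co, n_folds = 4, seed = 1)
  expect_false(any(plan$removed))
  expect_equal(nrow(attr(plan, "equalization_log")), 0L)
})

test_that("cross-validation pools scores and reports consistent counts", {
  co <- test_cohort(n = 160, genes = 40, informative = 5, seed = 22)
  ts <- derive_ts(co$patients$response)
  plan <- make_cv_plan(co, n_folds = 4, ts = ts, seed = 5)
  cv <- run_cv(co, plan, "smla-gbt", seed = 6, control = quick_control())

  expect_equal(nrow(cv$scores), sum(!plan$removed))
  expect_equal(sort(unique(cv$scores$fold)), 1:4)
  # pooled confusion counts cover every scored patient
  g <- glance(cv)
  expect_equal(g$n, nrow(cv$scores))
  expect_true(g$auc >= 0 && g$auc <= 1)
  pf <- tidy(cv)
  expect_equal(nrow(pf), 4)
  expect_true(all(pf$n > 0))
  # per-treatment metrics partition the pooled validation set
  expect_equal(sum(cv$metrics$per_treatment$n), nrow(cv$scores))
})

test_that("per-fold models never see validation patients", {
  co <- test_cohort(n = 140, genes = 30, informative = 4, seed = 41)
  ts <- derive_ts(co$patients$response)
  n <- n_patients(co)
  tr_idx <- 1:100
  va_idx <- 101:n

  train_sub <- cohort_subset(co, tr_idx)
  model_a <- train_mult(train_sub, ts = ts[tr_idx], seed = 9,
                        control = quick_control())

  # corrupt everything about the validation patients and retrain
  co2 <- co
  co2$clinical[va_idx, -1] <- co2$clinical[va_idx, -1] * 0 + 99
  co2$expression[va_idx, -1] <- co2$expression[va_idx, -1] * 0 + 99
  co2$patients$response[va_idx] <- "PD"
  model_b <- train_mult(cohort_subset(co2, tr_idx), ts = ts[tr_idx],
                        seed = 9, control = quick_control())

  expect_identical(tidy(model_a$sel_gene), tidy(model_b$sel_gene))
  expect_identical(model_a$norm_expr, model_b$norm_expr)
  expect_identical(model_a$profiling$centroids, model_b$profiling$centroids)
  expect_identical(model_a$denoiser$weights, model_b$denoiser$weights)
  expect_identical(model_a$tspt$threshold, model_b$tspt$threshold)
  raw_a <- lapply(model_a$tspt$members, xgboost::xgb.save.raw)
  raw_b <- lapply(model_b$tspt$members, xgboost::xgb.save.raw)
  expect_identical(raw_a, raw_b)
})

test_that("fold-level AUC comparison matches the t-test formula", {
  expect_equal(paired_auc_test(c(0.7, 0.8, 0.6), c(0.7, 0.8, 0.6)), 1)
  withr::with_seed(2, {
    a <- 0.9 + rnorm(10, sd = 1e-4)
    b <- 0.5 + rnorm(10, sd = 1e-4)
  })
  expect_lt(paired_auc_test(a, b), 1e-6)
  # textbook Welch formula oracle
  withr::with_seed(3, {
    x <- runif(8); y <- runif(8)
  })
  sp <- sqrt(var(x) / 8 + var(y) / 8)
  tstat <- (mean(x) - mean(y)) / sp
  df <- sp^4 / ((var(x) / 8)^2 / 7 + (var(y) / 8)^2 / 7)
  want <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(paired_auc_test(x, y), want, tolerance = 1e-10)
  expect_error(paired_auc_test(0.5, 0.5), "two folds")
})

test_that("the marker graph counts selections and co-selections", {
  mk_report <- function(markers, selected, role = "gene") {
    tbl <- tibble::tibble(
      marker = markers,
      p_value = seq(0.001, 0.4, length.out = length(markers)),
      status = ifelse(markers %in% selected, "selected",
                      "excluded_irrelevant"),
      redundant_to = NA_character_, role = role)
    class(tbl) <- c("mult_selection", class(tbl))
    tbl
  }
  all_m <- c("a", "b", "c", "d")
  reports <- c(
    replicate(10, mk_report(all_m, c("a", "b")), simplify = FALSE),
    list(mk_report(all_m, c("a", "c"))))
  g <- build_marker_graph(reports)

  sizes <- igraph::V(g)$size
  names(sizes) <- igraph::V(g)$name
  expect_equal(sizes[["a"]], 11)   # selected in all rounds
  expect_equal(sizes[["b"]], 10)
  expect_equal(sizes[["c"]], 1)
  expect_false("d" %in% igraph::V(g)$name)  # never selected

  # edge widths equal brute-force co-selection counts
  widths <- igraph::E(g)$width
  ends <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(ends))) {
    cnt <- sum(vapply(reports, function(r) {
      all(ends[i, ] %in% r$marker[r$status == "selected"])
    }, logical(1)))
    expect_equal(widths[i], cnt)
  }
  # b and c never co-selected: no such edge
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(build_marker_graph(list())), 0)
})
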