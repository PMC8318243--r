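test_that("log loss matches its closed form and an elementwise oracle", {
  expect_equal(log_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_lt(log_loss(c(1, 0, 1), c(1, 0, 1)), 1e-10)
  for (s in 1:20) {
    withr::with_seed(s, {
      y <- rbinom(50, 1, 0.4)
      p <- runif(50)
    })
    want <- -mean(vapply(seq_along(y), function(i) {
      y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i])
    }, numeric(1)))
    expect_equal(log_loss(y, p), want, tolerance = 1e-12)
  }
  expect_error(log_loss(c(1, 0), 0.5), "length")
})

test_that("the threshold rule matches an exhaustive-scan oracle", {
  # perfectly separated scores: any separating threshold, J = 1
  thr <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  expect_equal(attr(thr, "youden_j"), 1)

  # all-equal scores degenerate to that value with J = 0
  thr0 <- select_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(as.numeric(thr0), 0.4)
  expect_equal(attr(thr0, "youden_j"), 0)

  for (s in 1:40) {
    withr::with_seed(s, {
      sc <- round(runif(30), 2)  # duplicated scores exercise tie handling
      lb <- rbinom(30, 1, 0.5)
    })
    if (length(unique(lb)) < 2) next
    expect_equal(as.numeric(select_threshold(sc, lb)),
                 oracle_threshold(sc, lb), tolerance = 1e-12)
  }
  expect_error(select_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("Bayesian optimization recovers a known 1-D optimum", {
  space <- list(bo_real("x", 0, 1))
  for (s in 1:2) {
    res <- bayesian_optimize(space, function(h) (h$x - 0.3)^2,
                             n_init = 8, n_iter = 15, seed = s)
    expect_lt(abs(res$best$x - 0.3), 0.05)
    expect_equal(res$best_loss, min(res$trace$loss))
  }
  # determinism
  a <- bayesian_optimize(space, function(h) (h$x - 0.3)^2,
                         n_init = 4, n_iter = 4, seed = 42)
  b <- bayesian_optimize(space, function(h) (h$x - 0.3)^2,
                         n_init = 4, n_iter = 4, seed = 42)
  expect_identical(a$trace, b$trace)
})

test_that("failing objective evaluations are recorded and survived", {
  space <- list(bo_real("x", 0, 1))
  res <- bayesian_optimize(space, function(h) {
    if (h$x > 0.5) stop("boom") else h$x
  }, n_init = 6, n_iter = 6, seed = 3)
  expect_true(any(is.infinite(res$trace$loss)))
  expect_true(is.finite(res$best_loss))
  expect_lte(res$best$x, 0.5)
})

test_that("mixed-type spaces stay inside their declared ranges", {
  space <- hp_space("svm")
  res <- bayesian_optimize(space, function(h) {
    log(h$C) + as.numeric(h$kernel == "poly")
  }, n_init = 6, n_iter = 6, seed = 5)
  expect_true(all(res$trace$C >= 1e-2 & res$trace$C <= 1e3))
  expect_true(all(res$trace$kernel %in% c("linear", "poly", "rbf")))
  expect_true(all(res$trace$degree %in% 2:5))
})

make_signal_features <- function(n = 200, p = 10, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.4)
    x <- matrix(runif(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", 1:p)))
    x[, 1:3] <- x[, 1:3] + 0.35 * y
    x <- pmin(x, 1)
  })
  list(x = x, y = y)
}

test_that("the ensemble head learns planted signal and averages three members", {
  d <- make_signal_features(seed = 2)
  fit <- train_tspt(d$x, d$y, seed = 1, control = quick_control())
  expect_length(fit$members, 3)
  pred <- predict(fit, d$x)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_gt(multsens:::auc_mw(d$y, pred$score), 0.75)

  # ensemble score is the arithmetic mean of the member scores
  member_scores <- vapply(fit$members,
                          function(m) predict(m, d$x), numeric(nrow(d$x)))
  expect_equal(pred$score, rowMeans(member_scores), tolerance = 1e-12)

  # identical feature rows score identically
  same <- d$x[c(5, 5, 5), ]
  expect_equal(diff(range(predict(fit, same)$score)), 0)

  # hard labels follow the training-derived threshold
  expect_equal(pred$class,
               as.integer(pred$score >= as.numeric(fit$threshold)))
})

test_that("the three baseline backends run on the same selected features", {
  d <- make_signal_features(n = 120, seed = 4)
  for (backend in c("gbt", "mlp", "svm")) {
    fit <- train_smla(d$x, d$y, model = backend, alpha = 0.1,
                      seed = 2, control = quick_control())
    pred <- predict(fit, d$x)
    expect_true(all(is.finite(pred$score)))
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    expect_s3_class(fit$selection, "mult_selection")
  }
})

test_that("an empty selection aborts with actionable advice", {
  withr::with_seed(9, {
    x <- matrix(runif(60 * 5), 60, 5,
                dimnames = list(NULL, paste0("n", 1:5)))
    y <- rbinom(60, 1, 0.5)
  })
  expect_error(train_smla(x, y, model = "gbt", alpha = 1e-6, seed = 1,
                          control = quick_control()),
               "larger alpha")
})
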