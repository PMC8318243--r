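test_that("derive_ts maps response classes through the chosen cut", {
  def <- ts_definition("CR")
  expect_equal(derive_ts(c("CR", "VGPR", "SCR", "PD"), def),
               c(1L, 0L, 1L, 0L))
  # the shallowest admissible cut marks everything above PD sensitive
  expect_equal(derive_ts(c("SD", "PR", "SCR"), ts_definition("SD")),
               c(1L, 1L, 1L))
  expect_error(derive_ts("CRX", def), "unknown response class")
  expect_error(ts_definition("PD"), "must be one of")

  v <- c("PD", "SD", "PR", "VGPR", "CR", "SCR")
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(derive_ts(v, def)[perm], derive_ts(v[perm], def))
})

test_that("stratification p-value is calibrated and matches the log-rank test", {
  # identical survival distributions: no separation
  withr::with_seed(1, {
    time <- rexp(400, 1 / 500)
    event <- rbinom(400, 1, 0.8)
    ts <- rep(0:1, 200)
  })
  expect_gt(stratification_pvalue(ts, time, event), 0.05)

  # strong hazard separation is detected decisively
  for (s in 1:5) {
    withr::with_seed(s, {
      ts2 <- rep(0:1, each = 200)
      t2 <- rexp(400, ifelse(ts2 == 1, 1 / 1500, 1 / 500))
      cens <- rexp(400, 1 / 2000)
      ev2 <- as.integer(t2 <= cens)
      tt2 <- pmin(t2, cens)
    })
    expect_lt(stratification_pvalue(ts2, tt2, ev2), 0.001)
  }

  # agreement with an independent log-rank implementation (continuous
  # times, so tie handling cannot differ)
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      g <- rbinom(120, 1, 0.5)
      tt <- rexp(120, ifelse(g == 1, 1 / 900, 1 / 600))
      ev <- rbinom(120, 1, 0.85)
    })
    if (length(unique(g)) < 2 || any(tapply(ev, g, sum) == 0)) next
    p_cox <- stratification_pvalue(g, tt, ev)
    sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    p_lr <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
    expect_equal(p_cox, p_lr, tolerance = 1e-6)
  }

  expect_warning(p1 <- stratification_pvalue(rep(0:1, each = 10), rexp(20),
                                             rep(c(1, 0), each = 10)),
                 "no events")
  expect_equal(p1, 1)
  expect_error(stratification_pvalue(rep(1, 5), rexp(5), rep(1, 5)),
               "both groups")
})

test_that("the survival-guided cut recovers a planted CR/SCR hazard break", {
  co <- generate_cohort(synth_config(n_patients = 600, n_genes = 5,
                                     n_informative_genes = 0,
                                     hazard_ratio = 3, seed = 31))
  def <- select_ts_definition(co$patients$response,
                              co$patients$ddp_days,
                              co$patients$ddp_event)
  expect_equal(def$sensitive_from, "CR")
  expect_equal(nrow(def$p_table), 5)          # five and only five candidates
  expect_true(all(def$p_table$p_value >= 0 & def$p_table$p_value <= 1,
                  na.rm = TRUE))
  expect_equal(def$p_table$p_value[def$p_table$sensitive_from == "CR"],
               min(def$p_table$p_value, na.rm = TRUE))

  # derived outcome reproduces the planted sensitivity class
  ts_hat <- derive_ts(co$patients$response, def)
  expect_gte(mean(ts_hat == co$ground_truth$ts), 0.95)
})

test_that("survival-independent outcomes yield a full but uninformative table", {
  withr::with_seed(77, {
    resp <- sample(tr_classes(), 300, replace = TRUE)
    tt <- rexp(300, 1 / 700)
    ev <- rbinom(300, 1, 0.8)
  })
  def <- select_ts_definition(resp, tt, ev)
  expect_equal(nrow(def$p_table), 5)
  d2 <- select_ts_definition(resp, tt, ev)
  expect_identical(def$sensitive_from, d2$sensitive_from)  # deterministic
})
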