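test_that("arm-only Cox HR is symmetric under label swap and matches weighted fit", {
  st <- small_trial(n = 400, seed = 6)
  fit <- primary_cox_hr(st$ds)
  swapped <- st$ds
  swapped$data$arm <- factor(
    ifelse(swapped$data$arm == "control", "intervention", "control"),
    levels = c("control", "intervention"))
  fit_sw <- primary_cox_hr(swapped)
  expect_equal(fit_sw$hr, 1 / fit$hr, tolerance = 1e-8)
  wfit <- weighted_cox(st$ds$data$primary_time, st$ds$data$primary_event,
                       st$ds$data$arm, rep(1, 400))
  expect_equal(fit$loghr, wfit$loghr, tolerance = 1e-10)
})

test_that("null simulation keeps the HR near 1", {
  cfg <- synthetic_config(n_total = 3000, seed = 41, ate_loghr = 0,
                          missing_frac = 0)
  fit <- primary_cox_hr(generate_trial(cfg))
  expect_lt(abs(fit$loghr), 2 * fit$se)
})

test_that("win ratio counts a hand-checkable hierarchy", {
  # 2 intervention vs 2 control; tier1: c1 dies day 10, i1 survives past it;
  # i2 dies day 5 before c1 and c2 -> tier-1 contrasts decide three pairs
  d <- data.frame(
    id = c("i1", "i2", "c1", "c2"),
    arm = c("intervention", "intervention", "control", "control"),
    accrual_time = 0,
    primary_time = c(100, 5, 10, 100), primary_event = c(0L, 1L, 1L, 0L),
    safety_1_time = c(100, 5, 10, 100), safety_1_event = c(0L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
  ds <- trial_dataset(d, covariate_schema(character(), character()))
  wr <- win_ratio(ds)
  # pairs: (i1,c1) win; (i1,c2) tie; (i2,c1) loss; (i2,c2) loss
  expect_equal(wr$wins, 1)
  expect_equal(wr$losses, 2)
  expect_equal(wr$ties, 1)
  expect_equal(wr$wr, 0.5)
  expect_equal(wr$wins + wr$losses + wr$ties, 4)
})

test_that("identical arms give all ties and a flagged undefined ratio", {
  d <- data.frame(id = paste0("t", 1:6),
                  arm = rep(c("intervention", "control"), 3),
                  accrual_time = 0,
                  primary_time = rep(c(50, 50, 70), 2),
                  primary_event = rep(0L, 6),
                  safety_1_time = rep(c(50, 50, 70), 2),
                  safety_1_event = rep(0L, 6), stringsAsFactors = FALSE)
  ds <- trial_dataset(d, covariate_schema(character(), character()))
  wr <- win_ratio(ds)
  expect_true(wr$undefined)
  expect_equal(wr$ties, 9)
})

test_that("win-ratio CI covers 1 at the nominal rate under no difference", {
  cover <- sapply(1:200, function(s) {
    cfg <- synthetic_config(n_total = 120, seed = 5000 + s, ate_loghr = 0,
                            missing_frac = 0, n_safety = 2, censor_rate = 0.2)
    wr <- win_ratio(generate_trial(cfg))
    if (wr$undefined) return(NA)
    wr$ci_low <= 1 && wr$ci_high >= 1
  })
  cov_rate <- mean(cover, na.rm = TRUE)
  # binomial(200, 0.95): 0.95 +/- ~3 SE
  expect_gt(cov_rate, 0.90)
  expect_lt(cov_rate, 0.99)
})

test_that("balance and composition replicate on identical datasets", {
  st <- small_trial(n = 200, seed = 8)
  bc <- balance_and_composition(st$ds, st$ds, strata = c("b1", "c1"))
  expect_equal(bc$arm_p, 1)
  expect_equal(bc$shares$share_final, bc$shares$share_original)
})

test_that("period log-rank is 1 for identical subsets and calibrated under the null", {
  st <- small_trial(n = 300, seed = 9)
  pl <- period_logrank(st$ds, st$ds, period = c(0, Inf))
  expect_equal(pl$p, 1, tolerance = 1e-12)
  ps <- sapply(1:60, function(s) {
    cfg <- synthetic_config(n_total = 200, seed = 7000 + s, missing_frac = 0)
    ds <- generate_trial(cfg)
    ids <- split_half(ds, s)
    period_logrank(phenotrial:::subset_trial(ds, ids$train_ids),
                   phenotrial:::subset_trial(ds, ids$test_ids))$p
  })
  expect_lt(mean(ps < 0.05), 0.15)         # near the nominal 5% level
})

test_that("run summaries reproduce closed-form t statistics", {
  s0 <- summarize_runs(c(9, 10, 11), 10)
  expect_equal(s0$t, 0)
  expect_equal(s0$p, 1)
  s1 <- summarize_runs(c(8, 9, 10), 12)
  expect_equal(s1$t, -5.196152, tolerance = 1e-6)
  expect_equal(s1$p, 2 * pt(-5.196152, df = 2), tolerance = 1e-6)
  sz <- summarize_runs(c(7, 7, 7), 7)
  expect_true(sz$zero_variance)
  expect_equal(sz$p, 1)
  expect_error(summarize_runs(5, 5), ">= 2")
})
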