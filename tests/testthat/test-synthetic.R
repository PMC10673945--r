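test_that("generator is seed-deterministic and arms are near 1:1", {
  st1 <- small_trial(n = 500, seed = 9, missing = 0.05)
  st2 <- small_trial(n = 500, seed = 9, missing = 0.05)
  expect_identical(st1$ds$data, st2$ds$data)
  tab <- table(st1$ds$data$arm)
  expect_true(abs(tab[1] - tab[2]) <= 2 * sqrt(500))
})

test_that("control-arm event proportion is calibrated to control_rate", {
  cfg <- synthetic_config(n_total = 4000, seed = 21, censor_rate = 0,
                          missing_frac = 0, control_rate = 0.118,
                          ate_loghr = log(0.76))
  ds <- generate_trial(cfg)
  summ <- arm_event_summary(ds)
  p_hat <- summ$proportion[summ$arm == "control"]
  se <- sqrt(0.118 * 0.882 / summ$n[summ$arm == "control"])
  expect_lt(abs(p_hat - 0.118), 3 * se)
})

test_that("marginal Cox on a no-HTE simulation recovers the average effect", {
  cfg <- synthetic_config(n_total = 6000, seed = 5, missing_frac = 0)
  ds <- generate_trial(cfg)
  fit <- primary_cox_hr(ds)
  expect_lt(abs(fit$loghr - log(0.76)), 2 * fit$se)
})

test_that("a planted interaction is detectable at the population level", {
  st <- small_trial(n = 4000, seed = 13, hte = -0.5, missing = 0)
  d <- st$ds$data
  d$trt <- as.numeric(d$arm == "intervention")
  fit <- survival::coxph(survival::Surv(primary_time, primary_event) ~
                           trt * b1, data = d)
  p_int <- summary(fit)$coefficients["trt:b1", "Pr(>|z|)"]
  expect_lt(p_int, 0.05)
  expect_lt(coef(fit)[["trt:b1"]], 0)
})

test_that("true_individual_loghr reproduces the planted structure", {
  st0 <- small_trial(n = 100, seed = 2, missing = 0)
  expect_equal(unname(true_individual_loghr(st0$cfg, st0$ds)),
               rep(log(0.76), 100))
  st1 <- small_trial(n = 200, seed = 2, hte = -0.5, missing = 0)
  tl <- true_individual_loghr(st1$cfg, st1$ds)
  vals <- sort(unique(tl))
  expect_length(vals, 2)
  expect_equal(diff(vals), 0.5)
  # uses stored pre-missingness truth even when covariates are masked
  st2 <- small_trial(n = 200, seed = 2, hte = -0.5, missing = 0.3)
  expect_length(unique(true_individual_loghr(st2$cfg, st2$ds)), 2)
})

test_that("covariate shuffling preserves margins and outcomes", {
  st <- small_trial(n = 300, seed = 4, hte = -0.8, missing = 0.05)
  sh <- shuffle_covariates(st$ds, 99)
  for (nm in st$ds$schema$name) {
    expect_identical(sort(as.character(st$ds$data[[nm]]), na.last = TRUE),
                     sort(as.character(sh$data[[nm]]), na.last = TRUE))
  }
  for (col in c("arm", "accrual_time", "primary_time", "primary_event"))
    expect_identical(st$ds$data[[col]], sh$data[[col]])
  # arm-specific survival curves identical pre/post shuffle
  for (a in c("control", "intervention")) {
    f0 <- survival::survfit(survival::Surv(primary_time, primary_event) ~ 1,
                            data = st$ds$data[st$ds$data$arm == a, ])
    f1 <- survival::survfit(survival::Surv(primary_time, primary_event) ~ 1,
                            data = sh$data[sh$data$arm == a, ])
    expect_identical(f0$surv, f1$surv)
  }
})

test_that("shuffling destroys the covariate-treatment interaction on average", {
  st <- small_trial(n = 1000, seed = 6, hte = -0.8, missing = 0)
  coefs <- sapply(1:20, function(s) {
    d <- shuffle_covariates(st$ds, s)$data
    d$trt <- as.numeric(d$arm == "intervention")
    coef(survival::coxph(survival::Surv(primary_time, primary_event) ~
                           trt * b1, data = d))[["trt:b1"]]
  })
  expect_lt(abs(mean(coefs)), 2 * sd(coefs) / sqrt(20))
  # while the unshuffled interaction is materially negative
  d <- st$ds$data
  d$trt <- as.numeric(d$arm == "intervention")
  b_raw <- coef(survival::coxph(survival::Surv(primary_time, primary_event) ~
                                  trt * b1, data = d))[["trt:b1"]]
  expect_lt(b_raw, mean(coefs) - 2 * sd(coefs))
})
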