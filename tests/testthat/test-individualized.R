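test_that("unit weights reduce to the standard Cox estimator", {
  st <- small_trial(n = 200, seed = 3)
  d <- st$ds$data
  fit_w <- weighted_cox(d$primary_time, d$primary_event, d$arm)
  fit_ref <- survival::coxph(
    survival::Surv(primary_time, primary_event) ~ I(arm == "intervention"),
    data = d, ties = "breslow")
  expect_equal(fit_w$loghr, unname(coef(fit_ref)[1]), tolerance = 1e-6)
  expect_true(fit_w$converged)
  expect_gt(fit_w$se, 0)
})

test_that("zero weight on a participant equals refitting without them", {
  st <- small_trial(n = 100, seed = 4)
  d <- st$ds$data
  w <- rep(1, 100); w[7] <- 0
  fit_w <- weighted_cox(d$primary_time, d$primary_event, d$arm, w)
  fit_drop <- weighted_cox(d$primary_time[-7], d$primary_event[-7], d$arm[-7])
  expect_equal(fit_w$loghr, fit_drop$loghr, tolerance = 1e-9)
})

test_that("six-participant toy matches the brute-force likelihood oracle", {
  times <- c(0.8, 1.5, 2.0, 2.5, 4.0, 5.0)
  events <- c(1, 1, 1, 1, 0, 0)
  trt <- c(1, 0, 1, 0, 1, 0)
  w <- c(1, 0.5, 0.25, 1, 0.5, 1)
  fit <- weighted_cox(times, events, trt, w)
  beta_star <- grid_wcox_oracle(times, events, trt, w)
  expect_equal(fit$loghr, beta_star, tolerance = 1e-3)
})

test_that("no events in an arm flags non-convergence", {
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 0, 0)
  trt <- c(0, 0, 1, 1)   # no intervention events: monotone likelihood
  fit <- weighted_cox(times, events, trt)
  expect_false(fit$converged)
  expect_error(weighted_cox(times, events, trt, rep(0, 4)), "all-zero")
})

test_that("degenerate phenomap gives identical labels equal to pooled fit", {
  set.seed(5)
  n <- 60
  d <- data.frame(id = paste0("s", 1:n),
                  arm = rep(c("control", "intervention"), n / 2),
                  accrual_time = 0,
                  primary_time = rexp(n, 0.01) + 1,
                  primary_event = rep(c(1L, 0L, 1L), length.out = n),
                  same = rep(1, n), stringsAsFactors = FALSE)
  ds <- trial_dataset(d, covariate_schema("same", "binary"))
  map <- gower_matrix(frame = data.frame(same = factor(d$same)), ids = d$id)
  labels <- individualized_loghr(ds, map, interim_cut = 1e6)
  pooled <- weighted_cox(d$primary_time, d$primary_event, d$arm)
  expect_true(all(!is.na(labels$loghr)))
  expect_equal(unique(round(labels$loghr, 10)), round(pooled$loghr, 10))
})

test_that("labels recover the average effect under no heterogeneity", {
  st <- small_trial(n = 800, seed = 19, missing = 0)
  map <- gower_matrix(frame = st$ds$data[st$ds$schema$name],
                      ids = st$ds$data$id)
  labels <- individualized_loghr(st$ds, map, interim_cut = 1e6)
  pooled <- primary_cox_hr(st$ds)
  expect_gt(mean(!is.na(labels$loghr)), 0.9)
  expect_lt(abs(mean(labels$loghr, na.rm = TRUE) - log(0.76)),
            2 * pooled$se)
})

test_that("label contrast carries the sign of a planted interaction", {
  diffs <- sapply(1:8, function(s) {
    st <- small_trial(n = 500, seed = 100 + s, hte = -0.8, missing = 0)
    map <- gower_matrix(frame = st$ds$data[st$ds$schema$name],
                        ids = st$ds$data$id)
    labels <- individualized_loghr(st$ds, map, interim_cut = 1e6)
    carrier <- st$ds$data$b1 == 1
    mean(labels$loghr[carrier], na.rm = TRUE) -
      mean(labels$loghr[!carrier], na.rm = TRUE)
  })
  expect_lt(mean(diffs), 0)          # carriers look like better responders
  expect_gte(sum(diffs < 0), 5)      # and in most replicates
})

test_that("weighted fits match the grid oracle on random small instances", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 40) {
    n <- sample(4:8, 1)
    times <- round(rexp(n, 0.2) + 0.1, 3)
    events <- rbinom(n, 1, 0.7)
    trt <- rbinom(n, 1, 0.5)
    w <- sample(c(1, 0.5, 0.25), n, replace = TRUE)
    if (sum(events[trt == 1]) < 1 || sum(events[trt == 0]) < 1) next
    fit <- weighted_cox(times, events, trt, w)
    if (!fit$converged) next
    beta_star <- grid_wcox_oracle(times, events, trt, w)
    if (abs(beta_star) > 4.5) next   # maximizer outside the stable range
    expect_lt(abs(fit$loghr - beta_star), 1e-3)
    n_checked <- n_checked + 1
  }
})
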