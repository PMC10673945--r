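# Independent oracle for group-sequential boundaries: solve each look's
# boundary with mvtnorm::pmvnorm on the canonical joint normal
# (corr(Z_i, Z_j) = sqrt(t_i/t_j)), given the same spending increments.
mvtnorm_boundaries <- function(alpha, t, spending) {
  cum <- phenotrial:::spending_value(spending, alpha, t)
  cum[length(t)] <- if (t[length(t)] == 1) alpha else cum[length(t)]
  inc <- diff(c(0, cum))
  K <- length(t)
  corr <- outer(t, t, function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  b <- qnorm(1 - inc[1])
  if (K == 1) return(b)
  for (k in 2:K) {
    f <- function(x) {
      # P(Z_1 < b_1, ..., Z_{k-1} < b_{k-1}, Z_k >= x)
      no_rej_prev <- mvtnorm::pmvnorm(
        upper = c(b, x), corr = corr[1:k, 1:k],
        algorithm = mvtnorm::Miwa(steps = 512))[1]
      no_rej_all <- if (k == 2) pnorm(b) else mvtnorm::pmvnorm(
        upper = b, corr = corr[1:(k - 1), 1:(k - 1), drop = FALSE],
        algorithm = mvtnorm::Miwa(steps = 512))[1]
      (no_rej_all - no_rej_prev) - inc[k]
    }
    b <- c(b, uniroot(f, c(0.5, 8), tol = 1e-8)$root)
  }
  b
}

test_that("a single look reduces to the fixed-design critical value", {
  spec <- design_spec(4000)
  bd <- spending_boundaries(spec, 1.0)
  expect_equal(bd$boundary_z, qnorm(0.975), tolerance = 1e-6)
  expect_equal(bd$alpha_spent, 0.025)
})

test_that("four-look boundaries match the sequential-normal oracle", {
  t <- c(0.25, 0.5, 0.75, 1)
  for (sp in c("obrien_fleming", "pocock")) {
    spec <- design_spec(4000, spending = sp)
    bd <- spending_boundaries(spec, t)
    oracle <- mvtnorm_boundaries(0.025, t, sp)
    expect_lt(max(abs(bd$boundary_z - oracle)), 1e-3)
    expect_equal(sum(bd$alpha_increment), 0.025, tolerance = 1e-10)
  }
  # shape: OBF boundaries strictly decrease; Pocock near-constant
  obf <- spending_boundaries(design_spec(4000), t)$boundary_z
  expect_true(all(diff(obf) < 0))
  poc <- spending_boundaries(design_spec(4000, spending = "pocock"), t)$boundary_z
  expect_lt(max(poc) - min(poc), 0.12)
  # published Lan-DeMets O'Brien-Fleming values, one-sided 2.5%
  expect_equal(obf, c(4.3326, 2.9631, 2.3590, 2.0141), tolerance = 2e-3)
})

test_that("interim calendar times are event-count order statistics", {
  ds <- toy_trial()
  # event calendar times: 100, 270, 110, 170, 130 -> sorted 100,110,130,170,270
  expect_equal(interim_calendar_times(ds, c(3)), 130)
  expect_equal(interim_calendar_times(ds, c(1, 3, 5)), c(100, 130, 270))
  # adding an event after the trigger leaves earlier triggers unchanged
  d <- ds$data
  d <- rbind(d, within(d[1, ], { id <- "p9"; accrual_time <- 500
                                 primary_time <- 400; primary_event <- 1L }))
  ds2 <- trial_dataset(d, toy_schema())
  expect_equal(interim_calendar_times(ds2, c(3)), 130)
  expect_error(interim_calendar_times(ds, c(10)), "cannot reach")
})

test_that("Schoenfeld events formula evaluates in closed form", {
  spec <- design_spec(4000)
  rs <- required_sample(spec, 0.76)
  d_exact <- 4 * (qnorm(0.975) + qnorm(0.8))^2 / log(0.76)^2
  expect_equal(rs$d_required, ceiling(d_exact))
  expect_equal(rs$d_required, 417)
  # degenerate sanity: alpha 0.5 and power 0.5 -> zero z-sum -> 0 events
  spec0 <- design_spec(4000, alpha_one_sided = 0.499, power = 0.501)
  expect_lte(required_sample(spec0, 0.76)$d_required, 1)
  expect_equal(required_sample(spec, 1)$n_required, Inf)
  # N strictly decreases as the HR moves away from 1
  ns <- sapply(seq(0.95, 0.5, by = -0.05),
               function(h) required_sample(spec, h)$n_required)
  expect_true(all(diff(ns) < 0))
})

test_that("heterogeneity gate fails on constant predictions", {
  st <- small_trial(n = 200, seed = 2)
  g <- heterogeneity_gate(st$ds, setNames(rep(0.1, 200), st$ds$data$id), 1e6)
  expect_false(g$gate_passed)
  expect_true(is.na(g$interaction_p))
})

test_that("gate detects a strong planted interaction with high power", {
  passes <- sapply(1:15, function(s) {
    st <- small_trial(n = 2000, seed = 300 + s, hte = -0.8, missing = 0)
    preds <- setNames(true_individual_loghr(st$cfg, st$ds), st$ds$data$id)
    heterogeneity_gate(st$ds, preds, 1e6)$gate_passed
  })
  expect_gte(mean(passes), 0.8)
})

test_that("sample-size revision picks the q minimizing required N", {
  st <- small_trial(n = 2000, seed = 55, hte = -0.8, missing = 0)
  spec <- design_spec(n_planned = 4000)
  split <- split_half(st$ds, 1)
  test_ds <- phenotrial:::subset_trial(st$ds, split$test_ids)
  preds <- setNames(true_individual_loghr(st$cfg, test_ds), test_ds$data$id)
  enrolled <- phenotrial:::subset_trial(st$ds, split$train_ids)
  rev <- revise_under_enrichment(spec, enrolled, test_ds, preds, 1e6)
  expect_false(is.null(rev))
  expect_lte(rev$n_revised, spec$n_planned)
  accepted <- rev$grid[rev$grid$n_required <= spec$n_planned, ]
  expect_equal(rev$n_revised, min(accepted$n_required))
  expect_equal(rev$q_chosen,
               accepted$q[which.min(accepted$n_required)])
})

test_that("revision declines when no enrichment level is adequately powered", {
  # weak true effect and a tight planned size: required N stays above plan
  cfg <- synthetic_config(n_total = 1200, seed = 77, ate_loghr = log(0.95),
                          missing_frac = 0)
  ds <- generate_trial(cfg)
  spec <- design_spec(n_planned = 1200, intervention_rate = 0.112)
  split <- split_half(ds, 1)
  test_ds <- phenotrial:::subset_trial(ds, split$test_ids)
  set.seed(1)
  preds <- setNames(rnorm(600), test_ds$data$id)
  enrolled <- phenotrial:::subset_trial(ds, split$train_ids)
  rev <- revise_under_enrichment(spec, enrolled, test_ds, preds, 1e6)
  expect_null(rev)
})
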